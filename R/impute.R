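#' Multiple imputation by chained equations
#'
#' Fills missing values by iterated univariate conditional imputation and
#' returns `m` completed copies of the data. Each incomplete variable is
#' visited in turn (most-complete first) and imputed from all other variables:
#'
#' * numeric variables: predictive mean matching (PMM, type-1 matching,
#'   5 donors) with a Bayesian draw of the regression parameters;
#' * logical/binary variables: Bayesian logistic regression draws;
#' * ordered factors (e.g. diet-adherence categories): PMM on the integer
#'   codes — donors are observed rows, so imputed values are always valid
#'   observed categories and the ordinal structure is respected.
#'
#' Character columns and unordered factors with more than two levels are not
#' supported and should be recoded before imputation. Chains for the `m`
#' copies are run independently; results are reproducible under `seed`.
#'
#' @param data data frame to impute.
#' @param m number of completed copies; default 20.
#' @param iterations chained-equation sweeps per copy; default 10.
#' @param seed integer seed (`NULL` leaves the RNG stream alone).
#' @param exclude columns to carry through untouched and not use as
#'   predictors (identifiers); default `"participant_id"`.
#' @param donors PMM donor pool size; default 5.
#' @return An object of class `imputation_set`: list with `imputations`
#'   (list of `m` completed data frames), `m`, `iterations`, `seed`.
#' @export
mice_impute <- function(data, m = 20L, iterations = 10L, seed = NULL,
                        exclude = "participant_id", donors = 5L) {
  if (m < 1L) stop_gsm("bad_argument", "m must be at least 1")
  keep <- intersect(exclude, names(data))
  work <- data[, setdiff(names(data), keep), drop = FALSE]

  all_missing <- names(work)[vapply(work, function(x) all(is.na(x)), logical(1))]
  if (length(all_missing)) {
    stop_gsm("all_missing",
             paste("variable(s) 100% missing cannot be imputed:",
                   paste(all_missing, collapse = ", ")))
  }
  if (!any(!vapply(work, anyNA, logical(1)))) {
    stop_gsm("bad_argument", "at least one variable must be complete")
  }

  enc <- encode_columns(work)
  Z <- enc$Z
  miss <- is.na(Z)
  n_miss <- colSums(miss)
  to_impute <- names(sort(n_miss[n_miss > 0]))

  if (!is.null(seed)) set.seed(seed)
  imputations <- vector("list", m)
  for (copy in seq_len(m)) {
    Zc <- Z
    # initial fill: random draws from the observed values of each variable
    for (j in to_impute) {
      obs <- Zc[!miss[, j], j]
      Zc[miss[, j], j] <- sample(obs, sum(miss[, j]), replace = TRUE)
    }
    n_sweeps <- if (length(to_impute)) iterations else 0L
    for (it in seq_len(n_sweeps)) {
      for (j in to_impute) {
        mis_j <- miss[, j]
        X <- cbind(`(Intercept)` = 1, Zc[, setdiff(colnames(Zc), j), drop = FALSE])
        y_obs <- Z[!mis_j, j]
        if (enc$method[j] == "logreg") {
          Zc[mis_j, j] <- impute_logreg(X[!mis_j, , drop = FALSE], y_obs,
                                        X[mis_j, , drop = FALSE])
        } else {
          Zc[mis_j, j] <- impute_pmm(X[!mis_j, , drop = FALSE], y_obs,
                                     X[mis_j, , drop = FALSE], donors = donors)
        }
      }
    }
    out <- decode_columns(Zc, enc)
    for (nm in keep) out[[nm]] <- data[[nm]]
    imputations[[copy]] <- out[, names(data), drop = FALSE]
  }
  structure(list(imputations = imputations, m = m, iterations = iterations,
                 seed = seed),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set: m = %d completed copies, %d iterations, n = %d rows>\n",
              x$m, x$iterations, nrow(x$imputations[[1]])))
  invisible(x)
}

# ---- column encoding -------------------------------------------------------

# Internally the completed data live in a numeric matrix: logicals as 0/1,
# (ordered) factors as integer level codes, numerics as-is. Ordinal codes
# enter predictor matrices linearly; see the methods vignette.
encode_columns <- function(work) {
  method <- character(ncol(work))
  names(method) <- names(work)
  levels_list <- vector("list", ncol(work))
  names(levels_list) <- names(work)
  Z <- matrix(NA_real_, nrow = nrow(work), ncol = ncol(work),
              dimnames = list(NULL, names(work)))
  for (j in names(work)) {
    x <- work[[j]]
    if (is.logical(x)) {
      method[j] <- "logreg"
      Z[, j] <- as.numeric(x)
      levels_list[[j]] <- "logical"
    } else if (is.factor(x)) {
      if (nlevels(x) == 2L) {
        method[j] <- "logreg"
        Z[, j] <- as.numeric(x) - 1
      } else {
        method[j] <- "pmm"
        Z[, j] <- as.numeric(x)
      }
      levels_list[[j]] <- levels(x)
    } else if (is.numeric(x)) {
      method[j] <- "pmm"
      Z[, j] <- as.numeric(x)
      levels_list[[j]] <- "numeric"
    } else {
      stop_gsm("bad_argument",
               sprintf("column '%s' has unsupported type '%s' for imputation",
                       j, class(x)[1]))
    }
  }
  list(Z = Z, method = method, levels = levels_list,
       ordered = vapply(work, is.ordered, logical(1)))
}

decode_columns <- function(Zc, enc) {
  out <- vector("list", ncol(Zc))
  names(out) <- colnames(Zc)
  for (j in colnames(Zc)) {
    lv <- enc$levels[[j]]
    if (identical(lv, "logical")) {
      out[[j]] <- Zc[, j] > 0.5
    } else if (identical(lv, "numeric")) {
      out[[j]] <- Zc[, j]
    } else if (enc$method[j] == "logreg") {
      out[[j]] <- factor(lv[round(Zc[, j]) + 1], levels = lv,
                         ordered = enc$ordered[j])
    } else {
      out[[j]] <- factor(lv[round(Zc[, j])], levels = lv,
                         ordered = enc$ordered[j])
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# ---- univariate imputation draws ------------------------------------------

# Bayesian linear regression draw + type-1 predictive mean matching.
# A small proportional ridge stabilizes near-collinear predictors.
impute_pmm <- function(X_obs, y_obs, X_mis, donors = 5L) {
  n <- nrow(X_obs); p <- ncol(X_obs)
  S <- crossprod(X_obs)
  diag(S) <- diag(S) * (1 + 1e-5) + 1e-8
  R <- chol(S)
  betahat <- backsolve(R, backsolve(R, crossprod(X_obs, y_obs), transpose = TRUE))
  res <- y_obs - X_obs %*% betahat
  df <- max(n - p, 1)
  sigma2dot <- sum(res^2) / stats::rchisq(1, df)
  betadot <- betahat + sqrt(sigma2dot) * backsolve(R, stats::rnorm(p))
  yhat_obs <- as.numeric(X_obs %*% betahat)
  yhat_mis <- as.numeric(X_mis %*% betadot)
  y_obs[pmm_match(yhat_obs, yhat_mis, donors = donors)]
}

# For each target predicted value, pick one of the `donors` nearest observed
# predicted values (window search on the sorted donor predictions).
pmm_match <- function(yhat_obs, yhat_mis, donors = 5L) {
  n <- length(yhat_obs)
  donors <- min(donors, n)
  ord <- order(yhat_obs)
  yo <- yhat_obs[ord]
  pos <- findInterval(yhat_mis, yo)
  offs <- seq(-donors + 1L, donors)
  idx <- outer(pos, offs, "+")
  idx[idx < 1L] <- 1L
  idx[idx > n] <- n
  diffs <- abs(matrix(yo[idx], nrow = length(yhat_mis)) - yhat_mis)
  nm <- nrow(diffs)
  pick <- sample.int(donors, nm, replace = TRUE)
  chosen <- integer(nm)
  for (r in seq_len(donors)) {
    nb <- max.col(-diffs, ties.method = "first")
    sel <- which(pick == r)
    if (length(sel)) chosen[sel] <- idx[cbind(sel, nb[sel])]
    diffs[cbind(seq_len(nm), nb)] <- Inf
  }
  ord[chosen]
}

# Bayesian logistic regression draw; imputes Bernoulli(p) under drawn
# coefficients. Degenerate single-class observed data impute that class.
impute_logreg <- function(X_obs, y_obs, X_mis, maxit = 15L) {
  if (length(unique(y_obs)) < 2L) {
    return(rep(y_obs[1], nrow(X_mis)))
  }
  fit <- suppressWarnings(
    stats::glm.fit(X_obs, y_obs, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-6, maxit = maxit))
  )
  coefs <- fit$coefficients
  kept <- which(!is.na(coefs))
  qrr <- fit$qr
  r <- fit$rank
  Rmat <- qr.R(qrr)[seq_len(r), seq_len(r), drop = FALSE]
  # covariance of the kept (pivoted) coefficients: (R'R)^-1
  z <- stats::rnorm(r)
  delta <- backsolve(Rmat, z)
  piv <- qrr$pivot[seq_len(r)]
  betadot <- coefs
  betadot[is.na(betadot)] <- 0
  betadot[piv] <- betadot[piv] + delta
  eta <- as.numeric(X_mis %*% betadot)
  eta[eta > 30] <- 30; eta[eta < -30] <- -30
  as.numeric(stats::runif(length(eta)) < stats::plogis(eta))
}
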