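#' Partial least squares regression (PLS1, NIPALS)
#'
#' Mean-centred NIPALS PLS1: X is centred but not variance-scaled (the
#' absorbance scale is physically meaningful), y is centred. For each
#' component the weight vector is `w = X'y / ||X'y||`, scores `t = X w`,
#' y-loading `q = t'y / t't`, x-loading `p = X't / t't`, after which X and y
#' are deflated. The explained y sum of squares per component is
#' `SSY_a = q_a^2 t_a't_a`. With `n_components = "cv"` the component count
#' minimising the k-fold cross-validated RMSE is chosen, then shrunk by the
#' one-standard-error parsimony rule.
#'
#' @param X Samples-by-variables numeric matrix (e.g. [spectra_matrix()]).
#' @param y Numeric response, one scalar per sample.
#' @param n_components Integer count, or `"cv"`.
#' @param max_components Candidate ceiling for `"cv"`, default
#'   `min(n - 2, p, 10)`.
#' @param folds Number of CV folds (default 5).
#' @param cv_seed Seed controlling fold assignment (recorded on the model).
#' @return An object of class `ftir_plsr` with weights, scores, loadings,
#'   per-component explained y-variance `ssy`, fitted coefficients, and the
#'   CV table when `"cv"` was used.
#' @export
fit_plsr <- function(X, y, n_components = 2, max_components = NULL,
                     folds = 5, cv_seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) rlang::abort("`y` must have one value per row of X.")
  if (!all(is.finite(X))) rlang::abort("X must be finite.")
  if (stats::sd(y) == 0) rlang::abort("`y` is constant; PLSR is degenerate.")
  cv_table <- NULL
  if (identical(n_components, "cv")) {
    max_a <- max_components %||% min(n - 2, p, 10)
    if (max_a < 1) rlang::abort("Too few samples for cross-validation.")
    cv_table <- plsr_cv(X, y, max_a, folds, cv_seed)
    usable <- cv_table[is.finite(cv_table$rmse), ]
    if (nrow(usable) == 0) rlang::abort("Cross-validation produced no usable component count.")
    best <- which.min(usable$rmse)
    one_se <- usable$rmse[best] +
      ifelse(is.finite(usable$se[best]), usable$se[best], 0)
    n_components <- min(usable$n_components[usable$rmse <= one_se])
  }
  if (n_components < 1) rlang::abort("Need at least one component.")
  if (n < n_components + 2) {
    rlang::abort("Need n_samples >= n_components + 2.")
  }
  core <- nipals_pls1(X, y, n_components)
  structure(
    c(core, list(cv = cv_table, cv_seed = cv_seed, folds = folds)),
    class = "ftir_plsr"
  )
}

# Plain NIPALS PLS1 on centred data; truncates (with a flag) at numerical rank.
nipals_pls1 <- function(X, y, A) {
  n <- nrow(X); p <- ncol(X)
  x_center <- colMeans(X)
  y_center <- mean(y)
  E <- sweep(X, 2, x_center)
  f <- y - y_center
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, n, 0)
  q <- numeric(0)
  ssy <- numeric(0)
  truncated <- FALSE
  for (a in seq_len(A)) {
    w <- crossprod(E, f)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { truncated <- TRUE; break }
    w <- w / nw
    t_a <- E %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-24) { truncated <- TRUE; break }
    q_a <- sum(t_a * f) / tt
    p_a <- crossprod(E, t_a)[, 1] / tt
    E <- E - t_a %*% t(p_a)
    f <- f - q_a * t_a[, 1]
    W <- cbind(W, w); Tm <- cbind(Tm, t_a); P <- cbind(P, p_a)
    q <- c(q, q_a)
    ssy <- c(ssy, q_a^2 * tt)
  }
  A_used <- ncol(W)
  if (A_used == 0) rlang::abort("No usable PLS component (zero covariance).")
  # regression coefficients on the original (centred) X scale
  R <- W %*% solve(t(P) %*% W)
  beta <- R %*% q
  fitted <- y_center + (sweep(X, 2, x_center) %*% beta)[, 1]
  list(
    n_components = A_used, requested_components = A, truncated = truncated,
    weights = W, scores = Tm, x_loadings = P, y_loadings = q, ssy = ssy,
    coefficients = beta[, 1], x_center = x_center, y_center = y_center,
    fitted = fitted, residuals = y - fitted,
    wavenumbers = suppressWarnings(as.numeric(colnames(X)))
  )
}

plsr_cv <- function(X, y, max_a, folds, seed) {
  n <- nrow(X)
  fold_id <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  errs <- matrix(NA_real_, n, max_a)
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    if (all(hold) || !any(hold)) next
    a_max_k <- min(max_a, sum(!hold) - 1)
    fit <- nipals_pls1(X[!hold, , drop = FALSE], y[!hold], a_max_k)
    Ec <- sweep(X[hold, , drop = FALSE], 2, fit$x_center)
    # predictions with 1..A components via the coefficient recursions
    R <- fit$weights %*% solve(t(fit$x_loadings) %*% fit$weights)
    for (a in seq_len(fit$n_components)) {
      beta_a <- R[, seq_len(a), drop = FALSE] %*% fit$y_loadings[seq_len(a)]
      pred <- fit$y_center + (Ec %*% beta_a)[, 1]
      errs[hold, a] <- y[hold] - pred
    }
  }
  tibble::tibble(
    n_components = seq_len(max_a),
    rmse = apply(errs, 2, function(e) sqrt(mean(e^2, na.rm = TRUE))),
    se = apply(errs, 2, function(e) {
      stats::sd(e^2, na.rm = TRUE) / sqrt(sum(is.finite(e))) /
        (2 * sqrt(mean(e^2, na.rm = TRUE)))
    })
  )
}

#' @export
print.ftir_plsr <- function(x, ...) {
  cat(sprintf(
    "<ftir_plsr> %d component(s)%s, %d variables; R^2(train) = %.4f\n",
    x$n_components, if (x$truncated) " (rank-truncated)" else "",
    length(x$coefficients),
    1 - sum(x$residuals^2) / sum((x$fitted + x$residuals -
                                    mean(x$fitted + x$residuals))^2)
  ))
  invisible(x)
}

#' @method tidy ftir_plsr
#' @export
tidy.ftir_plsr <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    y_loading = x$y_loadings,
    ssy = x$ssy,
    ssy_fraction = x$ssy / sum(x$ssy)
  )
}

#' @method glance ftir_plsr
#' @export
glance.ftir_plsr <- function(x, ...) {
  y <- x$fitted + x$residuals
  tibble::tibble(
    n_components = x$n_components,
    truncated = x$truncated,
    r.squared = 1 - sum(x$residuals^2) / sum((y - mean(y))^2),
    rmse = sqrt(mean(x$residuals^2)),
    cv_rmse = if (!is.null(x$cv)) x$cv$rmse[x$cv$n_components == x$n_components] else NA_real_
  )
}

#' Predict from a PLS1 model
#'
#' @param object An `ftir_plsr`.
#' @param newdata Matrix with the same variables as the training X.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.ftir_plsr <- function(object, newdata, ...) {
  Ec <- sweep(as.matrix(newdata), 2, object$x_center)
  object$y_center + (Ec %*% object$coefficients)[, 1]
}

#' Variable importance in projection scores
#'
#' `VIP_j = sqrt( p * sum_a SSY_a w_aj^2 / sum_a SSY_a )` with unit-norm
#' weight vectors, so `sum_j VIP_j^2 = p` exactly. Wavenumbers whose score
#' exceeds the threshold (conventionally 1: more influential than the
#' average variable) are merged into contiguous influential intervals.
#'
#' @param model An `ftir_plsr`.
#' @param threshold Influence threshold, default 1.
#' @return An object of class `ftir_vip`: list with `scores` (tibble:
#'   `wavenumber`, `variable`, `vip`), `influential_bands` (tibble:
#'   `lo`, `hi`, `max_vip`) and `threshold`.
#' @export
vip_scores <- function(model, threshold = 1) {
  stopifnot(inherits(model, "ftir_plsr"))
  if (sum(model$ssy) <= 0) rlang::abort("Model explains no y-variance; VIP undefined.")
  W <- model$weights
  p <- nrow(W)
  wnorm2 <- colSums(W^2)  # unit by construction; kept for numerical honesty
  contrib <- sweep(W^2, 2, model$ssy / wnorm2, "*")
  vip <- unname(sqrt(p * rowSums(contrib) / sum(model$ssy)))
  wn <- model$wavenumbers
  scores <- tibble::tibble(
    wavenumber = if (all(is.finite(wn))) wn else NA_real_,
    variable = seq_len(p),
    vip = vip
  )
  structure(
    list(scores = scores,
         influential_bands = vip_intervals(scores, threshold),
         threshold = threshold),
    class = "ftir_vip"
  )
}

vip_intervals <- function(scores, threshold) {
  hot <- scores$vip > threshold
  if (!any(hot)) {
    return(tibble::tibble(lo = numeric(0), hi = numeric(0),
                          max_vip = numeric(0)))
  }
  idx <- which(hot)
  grp <- cumsum(c(1, diff(idx) != 1))
  key <- if (all(is.finite(scores$wavenumber))) scores$wavenumber else scores$variable
  purrr::map_dfr(split(idx, grp), function(ii) {
    tibble::tibble(lo = min(key[ii]), hi = max(key[ii]),
                   max_vip = max(scores$vip[ii]))
  })
}

#' @export
print.ftir_vip <- function(x, ...) {
  cat(sprintf("<ftir_vip> %d variables, %d influential interval(s) above %.2f\n",
              nrow(x$scores), nrow(x$influential_bands), x$threshold))
  if (nrow(x$influential_bands)) print(x$influential_bands)
  invisible(x)
}

#' @method tidy ftir_vip
#' @export
tidy.ftir_vip <- function(x, ...) x$scores

#' @method autoplot ftir_vip
#' @export
autoplot.ftir_vip <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$wavenumber, .data$vip)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "VIP score") +
    ggplot2::theme_minimal()
}

#' Annotate influential VIP intervals with band assignments
#'
#' Maps each influential wavenumber interval to the named vibrational bands
#' whose windows it overlaps, or `"unassigned"`.
#'
#' @param vip An `ftir_vip`.
#' @param band_table Band table, default [default_band_table()].
#' @return Tibble: `lo`, `hi`, `max_vip`, `bands` (comma-separated names).
#' @export
band_report <- function(vip, band_table = default_band_table()) {
  stopifnot(inherits(vip, "ftir_vip"))
  iv <- vip$influential_bands
  if (nrow(iv) == 0) return(dplyr::mutate(iv, bands = character(0)))
  iv$bands <- vapply(seq_len(nrow(iv)), function(i) {
    hw <- pmax(band_table$sigma_hi, band_table$center_tol)
    hit <- band_table$center + hw >= iv$lo[i] &
      band_table$center - hw <= iv$hi[i]
    if (any(hit)) paste(band_table$name[hit], collapse = ",") else "unassigned"
  }, "")
  iv
}
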