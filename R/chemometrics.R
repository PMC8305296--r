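#' Aligned GC-MS peak table
#'
#' Container for an aligned untargeted volatile peak table: a samples x
#' variables matrix of positive peak areas, a class label per sample
#' (e.g. cooked / AD / VD / FD), optional retention times per variable and
#' an optional internal-standard column id.
#'
#' @param areas numeric matrix, samples in rows, volatile variables in
#'   columns; all areas `>= 0`. Row and column names are generated when
#'   absent.
#' @param class character or factor of sample class labels, one per row.
#' @param rt optional numeric vector of retention times (min), one per
#'   variable.
#' @param internal_standard optional column name of the internal standard.
#' @return Object of class `"peak_table"`.
#' @export
peak_table <- function(areas, class, rt = NULL, internal_standard = NULL) {
  areas <- as.matrix(areas)
  if (any(areas < 0)) stop("peak areas cannot be negative")
  if (length(class) != nrow(areas))
    stop("one class label per sample (row) is required")
  if (is.null(rownames(areas)))
    rownames(areas) <- sprintf("s%02d", seq_len(nrow(areas)))
  if (is.null(colnames(areas)))
    colnames(areas) <- sprintf("v%03d", seq_len(ncol(areas)))
  if (!is.null(rt)) {
    if (length(rt) != ncol(areas)) stop("one retention time per variable")
    rt <- stats::setNames(as.numeric(rt), colnames(areas))
  }
  if (!is.null(internal_standard) && !internal_standard %in% colnames(areas))
    stop("internal standard column not found: ", internal_standard)
  structure(list(areas = areas,
                 class = factor(class, levels = unique(as.character(class))),
                 rt = rt, internal_standard = internal_standard),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("Peak table: %d samples x %d variables, classes: %s\n",
              nrow(x$areas), ncol(x$areas),
              paste(sprintf("%s (%d)", levels(x$class), table(x$class)),
                    collapse = ", ")))
  if (!is.null(x$internal_standard))
    cat("  internal standard:", x$internal_standard, "\n")
  invisible(x)
}

#' Linear retention index from an alkane ladder
#'
#' Temperature-programmed (linear) retention index: a compound eluting
#' between the bracketing n-alkanes with carbon numbers `c_n` and `c_(n+1)`
#' gets `RI = 100 * (c_n + (c_(n+1) - c_n) * (rt - t_n) / (t_(n+1) - t_n))`.
#'
#' @param rt retention time(s) of the compound(s), minutes; vectorised.
#' @param carbons ordered integer carbon numbers of the alkane standards
#'   (e.g. 8:22).
#' @param rt_alkanes strictly increasing retention times (min) of those
#'   alkanes.
#' @param extrapolate allow `rt` outside the ladder span (linear
#'   extrapolation from the nearest segment); off by default.
#' @return Retention indices (100 x carbon-number units).
#' @examples
#' retention_index(21.5, c(14, 15), c(20, 22))  # 1475
#' @export
retention_index <- function(rt, carbons, rt_alkanes, extrapolate = FALSE) {
  stopifnot(length(carbons) == length(rt_alkanes), length(carbons) >= 2L)
  if (any(diff(carbons) <= 0) || any(diff(rt_alkanes) <= 0))
    stop("alkane ladder must have increasing carbon numbers and times")
  out_of_span <- rt < rt_alkanes[1L] | rt > rt_alkanes[length(rt_alkanes)]
  if (any(out_of_span) && !extrapolate)
    stop("retention time outside the alkane ladder span; ",
         "set extrapolate = TRUE to extrapolate")
  i <- findInterval(rt, rt_alkanes, all.inside = TRUE)
  100 * (carbons[i] + (carbons[i + 1L] - carbons[i]) *
           (rt - rt_alkanes[i]) / (rt_alkanes[i + 1L] - rt_alkanes[i]))
}

#' Internal-standard normalisation of a peak table
#'
#' Divides every sample's peak areas by that sample's internal-standard
#' area, then removes the internal-standard column.
#'
#' @param table a [peak_table].
#' @param internal_standard column name of the internal standard; defaults
#'   to the one recorded in the table.
#' @return A new `peak_table` without the internal-standard column.
#' @export
normalize_peaks <- function(table, internal_standard = NULL) {
  stopifnot(inherits(table, "peak_table"))
  is_id <- if (is.null(internal_standard)) table$internal_standard
           else internal_standard
  if (is.null(is_id)) stop("no internal standard recorded or supplied")
  if (!is_id %in% colnames(table$areas))
    stop("internal standard column not found: ", is_id)
  is_area <- table$areas[, is_id]
  if (any(is_area <= 0)) stop("internal-standard area must be positive in every sample")
  keep <- setdiff(colnames(table$areas), is_id)
  peak_table(table$areas[, keep, drop = FALSE] / is_area,
             class = table$class,
             rt = if (!is.null(table$rt)) table$rt[keep])
}

#' Per-sample total peak area, with optional group comparison
#'
#' Sums all volatile peak areas per sample. With `compare = TRUE` the totals
#' are compared across classes via [group_compare] (ANOVA + pairwise t-tests
#' + letters), the way total volatile abundance is compared between
#' treatments.
#'
#' @param table a [peak_table].
#' @param compare also run the group comparison.
#' @return Named vector of totals, or (with `compare`) a list with `totals`
#'   and the `group_comparison`.
#' @export
total_peak_area <- function(table, compare = FALSE) {
  stopifnot(inherits(table, "peak_table"))
  totals <- rowSums(table$areas)
  if (!compare) return(totals)
  list(totals = totals, comparison = group_compare(totals, table$class))
}

# ---- PLS-DA ----------------------------------------------------------------

#' PLS-DA by NIPALS
#'
#' Partial least squares discriminant analysis: the class factor is one-hot
#' encoded into a dummy response matrix and a PLS2 regression is computed by
#' the NIPALS algorithm, extracting latent variables sequentially with
#' deflation of both blocks. Columns of X are autoscaled (centred, unit
#' variance) by default, the standard preprocessing for GC-MS fingerprints;
#' constant columns are dropped with a warning. The algorithm is fully
#' deterministic: refitting identical input yields an identical model.
#'
#' @param x numeric matrix (samples x variables) or a [peak_table].
#' @param y class factor, one level per treatment; taken from the peak
#'   table when `x` is one.
#' @param ncomp number of latent variables to extract.
#' @param center,scale column preprocessing of X (autoscaling on by default).
#' @param max_iter,tol NIPALS inner-loop controls.
#' @return Object of class `"plsda"`: X-scores `T`, weights `W`, loadings
#'   `P`, Y-loadings `Q`, the preprocessing record, per-LV explained
#'   variance for X and Y (`R2X`, `R2Y`), fitted class reconstruction and
#'   regression coefficients. Supports `print`, `predict`, `plot` (bi-plot).
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 2), 10))
#' fit <- plsda(x, rep(c("a", "b"), each = 10), ncomp = 2)
#' fit$R2Y
#' @export
plsda <- function(x, y = NULL, ncomp = 2L, center = TRUE, scale = TRUE,
                  max_iter = 500L, tol = 1e-10) {
  if (inherits(x, "peak_table")) {
    if (is.null(y)) y <- x$class
    x <- x$areas
  }
  x <- as.matrix(x)
  y <- factor(y, levels = unique(as.character(y)))
  if (nlevels(y) < 2L) stop("discriminant analysis needs >= 2 classes")
  if (nrow(x) != length(y)) stop("one class label per sample is required")
  if (ncomp > min(nrow(x) - 1L, ncol(x)))
    stop("ncomp cannot exceed min(samples - 1, variables)")

  sds <- apply(x, 2L, stats::sd)
  drop <- sds == 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " constant variable(s) before PLS-DA")
    x <- x[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  mu <- colMeans(x)
  ctr <- if (center) mu else rep(0, ncol(x))
  scl <- if (scale) sds else rep(1, ncol(x))
  X0 <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  Ydum <- stats::model.matrix(~ y - 1)
  colnames(Ydum) <- levels(y)
  ymu <- colMeans(Ydum)
  Y0 <- sweep(Ydum, 2L, ymu)

  n <- nrow(X0); p <- ncol(X0); g <- ncol(Y0)
  X <- X0; Y <- Y0
  ssx <- sum(X0^2); ssy <- sum(Y0^2)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); Q <- matrix(0, g, ncomp)
  r2x <- r2y <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(X, u))
      w <- w / sqrt(sum(w^2))
      tt <- drop(X %*% w)
      q <- drop(crossprod(Y, tt)) / sum(tt^2)
      u <- drop(Y %*% q) / sum(q^2)
      if (sum((tt - t_old)^2) < tol^2 * sum(tt^2)) break
      t_old <- tt
    }
    pp <- drop(crossprod(X, tt)) / sum(tt^2)
    X <- X - tcrossprod(tt, pp)
    Y <- Y - tcrossprod(tt, q)
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; Q[, a] <- q
    r2x[a] <- sum(tt^2) * sum(pp^2) / ssx
    r2y[a] <- sum(tt^2) * sum(q^2) / ssy
  }
  dimnames(W) <- dimnames(P) <- list(colnames(X0), paste0("LV", seq_len(ncomp)))
  dimnames(Tm) <- list(rownames(x), paste0("LV", seq_len(ncomp)))
  dimnames(Q) <- list(levels(y), paste0("LV", seq_len(ncomp)))
  B <- W %*% solve(crossprod(P, W)) %*% t(Q)
  Yhat0 <- Tm %*% t(Q)                       # reconstructed centred membership
  structure(list(ncomp = ncomp, T = Tm, W = W, P = P, Q = Q, B = B,
                 X0 = X0, Y0 = Y0, Yhat0 = Yhat0,
                 R2X = r2x, R2Y = r2y,
                 preprocessing = list(center = ctr, scale = scl,
                                      y_center = ymu, dropped = names(drop)[drop]),
                 classes = levels(y), y = y),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA (NIPALS), %d LVs, %d samples x %d variables, %d classes\n",
              x$ncomp, nrow(x$T), nrow(x$W), length(x$classes)))
  cat("explained variance per LV:\n")
  print(round(rbind(X = x$R2X, Y = x$R2Y) * 100, 1))
  invisible(x)
}

#' Predict class membership from a PLS-DA model
#'
#' @param object a [plsda] model.
#' @param newdata matrix of raw (unpreprocessed) variables, or a
#'   [peak_table]; defaults to the training data.
#' @param ncomp number of latent variables to use (`<= object$ncomp`).
#' @param type `"class"` for hard assignments, `"response"` for the
#'   predicted dummy-membership matrix.
#' @param ... unused.
#' @export
predict.plsda <- function(object, newdata = NULL,
                          ncomp = object$ncomp,
                          type = c("class", "response"), ...) {
  type <- match.arg(type)
  stopifnot(ncomp >= 1L, ncomp <= object$ncomp)
  Xs <- if (is.null(newdata)) object$X0 else {
    if (inherits(newdata, "peak_table")) newdata <- newdata$areas
    newdata <- as.matrix(newdata)[, rownames(object$W), drop = FALSE]
    sweep(sweep(newdata, 2L, object$preprocessing$center), 2L,
          object$preprocessing$scale, "/")
  }
  a <- seq_len(ncomp)
  Ba <- object$W[, a, drop = FALSE] %*%
    solve(crossprod(object$P[, a, drop = FALSE],
                    object$W[, a, drop = FALSE])) %*%
    t(object$Q[, a, drop = FALSE])
  yhat <- sweep(Xs %*% Ba, 2L, object$preprocessing$y_center, "+")
  colnames(yhat) <- object$classes
  if (type == "response") return(yhat)
  factor(object$classes[max.col(yhat, ties.method = "first")],
         levels = object$classes)
}

#' Choose the number of latent variables by leave-one-out accuracy
#'
#' Operationalises "the lowest number of latent variables resulting in
#' class separation" as the smallest `ncomp` whose leave-one-out class
#' assignment accuracy reaches 100%, falling back to the `ncomp` with the
#' highest accuracy when perfect separation is never reached.
#'
#' @param x matrix or [peak_table]; @param y class factor (from the table
#'   when omitted).
#' @param max_ncomp largest model size tried.
#' @param ... passed on to [plsda].
#' @return List with `ncomp` (chosen) and `accuracy` (per candidate size).
#' @export
plsda_ncomp <- function(x, y = NULL, max_ncomp = 3L, ...) {
  if (inherits(x, "peak_table")) {
    if (is.null(y)) y <- x$class
    x <- x$areas
  }
  x <- as.matrix(x)
  y <- factor(y, levels = unique(as.character(y)))
  n <- nrow(x)
  max_ncomp <- min(max_ncomp, n - 2L, ncol(x))
  hits <- matrix(FALSE, n, max_ncomp)
  for (i in seq_len(n)) {
    fit <- plsda(x[-i, , drop = FALSE], y[-i], ncomp = max_ncomp, ...)
    for (a in seq_len(max_ncomp))
      hits[i, a] <- predict(fit, x[i, , drop = FALSE], ncomp = a) == y[i]
  }
  acc <- colMeans(hits)
  ncomp <- if (any(acc == 1)) which(acc == 1)[1L] else which.max(acc)
  list(ncomp = as.integer(ncomp), accuracy = acc)
}

# ---- VID -------------------------------------------------------------------

#' Variable identification (VID) coefficients
#'
#' Quantifies the discriminant power of each volatile for each class as the
#' Pearson correlation between the variable's autoscaled column and the
#' PLS-DA model's reconstructed class-membership column for that class.
#' Values lie in `[-1, 1]`; a positive VID marks a compound more abundant
#' in that class than in the others, a negative one less abundant. This is
#' a deliberate reconstruction of the VID measure used with PLS-DA in
#' volatile fingerprinting; it reproduces the stated sign interpretation
#' and yields VID = 1 for a variable identical to the class indicator.
#'
#' @param model a fitted [plsda].
#' @return Matrix of class `"vid_table"`, variables x classes.
#' @export
vid_coefficients <- function(model) {
  stopifnot(inherits(model, "plsda"))
  v <- stats::cor(model$X0, model$Yhat0)
  colnames(v) <- model$classes
  structure(v, class = c("vid_table", class(v)))
}

#' Select discriminant compounds from a VID table
#'
#' Keeps, per class, the variables whose absolute VID exceeds the threshold
#' (0.8 by convention) and lists them in decreasing order of VID, negative
#' discriminants last — the layout of a discriminant-compound table.
#'
#' @param vid a [vid_coefficients] result (or any variables x classes
#'   matrix of VID values).
#' @param threshold absolute VID above which a compound is discriminant.
#' @return Data frame with columns `class`, `variable`, `VID`.
#' @export
select_discriminants <- function(vid, threshold = 0.8) {
  stopifnot(is.matrix(vid), threshold >= 0)
  out <- lapply(colnames(vid), function(cl) {
    v <- vid[, cl]
    sel <- which(abs(v) > threshold)
    if (!length(sel)) return(NULL)
    sel <- sel[order(-v[sel])]
    data.frame(class = cl, variable = rownames(vid)[sel], VID = unname(v[sel]))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(class = character(), variable = character(),
                      VID = numeric())
  rownames(out) <- NULL
  out
}

#' Bi-plot coordinates for a PLS-DA model
#'
#' Sample scores and correlation loadings on a pair of latent variables,
#' for the conventional bi-plot: variables are placed at their correlation
#' with each score (so everything lives in the unit disc), class dummy
#' columns give the class vectors, and the 70% / 100% correlation circles
#' mark how much of a variable's variance the two LVs explain.
#'
#' @param model a fitted [plsda].
#' @param lv integer pair of latent variables, default `c(1, 2)`.
#' @return List with `scores` (samples x 2), `variables` (correlation
#'   loadings, variables x 2), `classes` (class-vector loadings),
#'   `circle_radii` (`c(inner = 0.7, outer = 1)`) and `explained`
#'   (percent X and Y variance of the two LVs).
#' @export
biplot_coordinates <- function(model, lv = c(1L, 2L)) {
  stopifnot(inherits(model, "plsda"), length(lv) == 2L)
  if (any(lv > model$ncomp)) stop("requested LV beyond the fitted model")
  Tm <- model$T[, lv, drop = FALSE]
  list(scores = Tm,
       variables = stats::cor(model$X0, Tm),
       classes = stats::cor(model$Y0, Tm),
       circle_radii = c(inner = 0.7, outer = 1),
       explained = list(X = 100 * model$R2X[lv], Y = 100 * model$R2Y[lv]))
}

#' @export
plot.plsda <- function(x, lv = c(1L, 2L), ...) {
  bc <- biplot_coordinates(x, lv)
  th <- seq(0, 2 * pi, length.out = 200)
  sc <- bc$scores / max(abs(bc$scores))       # scale scores into the unit disc
  cols <- grDevices::hcl.colors(length(x$classes), "Dark 3")
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 xlab = sprintf("LV%d (X %.1f%%, Y %.1f%%)", lv[1L],
                                bc$explained$X[1L], bc$explained$Y[1L]),
                 ylab = sprintf("LV%d (X %.1f%%, Y %.1f%%)", lv[2L],
                                bc$explained$X[2L], bc$explained$Y[2L]),
                 main = "PLS-DA bi-plot", ...)
  graphics::lines(cos(th), sin(th), col = "grey60")
  graphics::lines(0.7 * cos(th), 0.7 * sin(th), col = "grey80", lty = 2)
  graphics::points(bc$variables, pch = 1, col = "grey40")
  graphics::points(sc, pch = 16, col = cols[as.integer(x$y)])
  for (k in seq_along(x$classes))
    graphics::arrows(0, 0, bc$classes[k, 1L], bc$classes[k, 2L],
                     length = 0.08, col = cols[k], lwd = 2)
  graphics::legend("topright", legend = x$classes, col = cols, pch = 16,
                   bty = "n", cex = 0.8)
  invisible(x)
}
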