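# Group comparison of replicate quality measurements (colour, hardness,
# enthalpies, yields): one-way ANOVA followed by pairwise t-tests and a
# compact letter display, matching the superscript-letter convention of
# quality tables.

# Greedy insert-and-absorb compact letter display from a symmetric p-value
# matrix: start with one letter covering everything, split it whenever a
# significant pair shares a letter, then absorb redundant letters. Groups
# sharing a letter are not significantly different at alpha.
.cld_letters <- function(pmat, alpha = 0.05) {
  g <- nrow(pmat)
  sets <- list(seq_len(g))                 # each set = indices sharing a letter
  for (i in seq_len(g - 1L)) {
    for (j in seq(i + 1L, g)) {
      if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
      split <- list()
      for (s in seq_along(sets)) {
        if (i %in% sets[[s]] && j %in% sets[[s]]) {
          split[[length(split) + 1L]] <- setdiff(sets[[s]], j)
          split[[length(split) + 1L]] <- setdiff(sets[[s]], i)
        } else {
          split[[length(split) + 1L]] <- sets[[s]]
        }
      }
      # absorb: drop any set contained in another (keeps one copy of dups)
      keep <- rep(TRUE, length(split))
      for (s in seq_along(split)) {
        for (r in seq_along(split)) {
          if (s == r || !keep[r]) next
          if (all(split[[s]] %in% split[[r]]) &&
              (length(split[[s]]) < length(split[[r]]) || s > r)) {
            keep[s] <- FALSE
            break
          }
        }
      }
      sets <- split[keep]
    }
  }
  # letters ordered by the first group each covers
  sets <- sets[order(vapply(sets, min, 0L))]
  out <- character(g)
  for (s in seq_along(sets))
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  out
}

#' Compare replicate groups with ANOVA, t-tests and letters
#'
#' One-way ANOVA across treatment groups followed by pairwise Student
#' t-tests at level `alpha` (Welch by default; set `pool_sd = TRUE` for the
#' classical pooled-variance test) and a compact letter display: groups
#' sharing a letter are not significantly different. No multiple-testing
#' correction is applied by default, mirroring common practice in quality
#' tables; pass e.g. `p_adjust = "holm"` to change that.
#'
#' @param values numeric vector of replicate measurements.
#' @param groups factor or character vector of the same length labelling
#'   the treatment of each replicate; at least two groups with two or more
#'   replicates each.
#' @param alpha significance level for the letter display.
#' @param pool_sd use a pooled variance estimate in the pairwise t-tests.
#' @param p_adjust multiple-testing correction passed to
#'   [stats::pairwise.t.test] (default `"none"`).
#' @return Object of class `"group_comparison"`: a list with `table`
#'   (group, n, mean, sd, letters), `anova` (F statistic and p-value),
#'   `p_matrix` (pairwise p-values) and the settings used.
#' @examples
#' set.seed(1)
#' v <- c(rnorm(6, 10), rnorm(6, 10), rnorm(6, 18))
#' g <- rep(c("AD", "VD", "FD"), each = 6)
#' group_compare(v, g)
#' @export
group_compare <- function(values, groups, alpha = 0.05, pool_sd = FALSE,
                          p_adjust = "none") {
  groups <- factor(groups, levels = unique(as.character(groups)))
  if (length(values) != length(groups)) stop("values and groups lengths differ")
  if (nlevels(groups) < 2L) stop("need at least two groups")
  n_per <- tapply(values, groups, length)
  if (any(n_per < 2L)) stop("every group needs >= 2 replicates")
  if (all(tapply(values, groups, stats::sd) == 0))
    stop("zero within-group variance everywhere: tests are degenerate")

  aovfit <- stats::aov(values ~ groups)
  atab <- summary(aovfit)[[1L]]
  pt <- stats::pairwise.t.test(values, groups, p.adjust.method = p_adjust,
                               pool.sd = pool_sd)
  lv <- levels(groups)
  pmat <- matrix(NA_real_, nlevels(groups), nlevels(groups),
                 dimnames = list(lv, lv))
  for (i in rownames(pt$p.value)) for (j in colnames(pt$p.value)) {
    if (!is.na(pt$p.value[i, j])) {
      pmat[i, j] <- pt$p.value[i, j]
      pmat[j, i] <- pt$p.value[i, j]
    }
  }
  letters_ <- .cld_letters(pmat, alpha)
  tab <- data.frame(group = lv,
                    n = as.integer(n_per[lv]),
                    mean = as.numeric(tapply(values, groups, mean)[lv]),
                    sd = as.numeric(tapply(values, groups, stats::sd)[lv]),
                    letters = letters_)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 anova = list(F = atab$`F value`[1L], p = atab$`Pr(>F)`[1L],
                              df = atab$Df),
                 p_matrix = pmat, alpha = alpha, pool_sd = pool_sd,
                 p_adjust = p_adjust),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.4g\n", x$anova$F, x$anova$p))
  cat(sprintf("Pairwise %s t-tests (%s correction), alpha = %g\n",
              if (x$pool_sd) "pooled" else "Welch", x$p_adjust, x$alpha))
  tab <- x$table
  tab$mean <- signif(tab$mean, digits)
  tab$sd <- signif(tab$sd, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Format a quality table with significance letters
#'
#' Renders a [group_compare] result as the conventional
#' `mean +/- sd ^letter^` strings of a quality-attribute table.
#'
#' @param x a `group_comparison`.
#' @param digits significant digits for mean and sd.
#' @return Named character vector, one entry per group.
#' @export
format_mean_sd <- function(x, digits = 4) {
  stopifnot(inherits(x, "group_comparison"))
  tab <- x$table
  stats::setNames(sprintf("%s ± %s ^%s^",
                          signif(tab$mean, digits), signif(tab$sd, digits),
                          tab$letters),
                  tab$group)
}
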