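#' Group testing cascade on principal-component scores
#'
#' For each score column: Shapiro-Wilk normality p-value; a Kruskal-Wallis
#' test across all groups; and all pairwise Welch t-tests. P-values are
#' reported raw (uncorrected) by default, matching the convention of
#' reporting each pairwise contrast at the 0.05 level; Holm correction is
#' available via `p_adjust`.
#'
#' @param scores numeric vector (PC1) or matrix with one column per
#'   component.
#' @param groups factor/character of group labels (e.g. the four sex x age
#'   groups), at least 3 subjects per group.
#' @param alpha significance level for flagging (default 0.05).
#' @param p_adjust multiple-comparison correction for the pairwise Welch
#'   tests: `"none"` (default) or any method of [stats::p.adjust()].
#' @return object of class `group_test_report`: list with per-component
#'   entries, each holding `shapiro_p`, `kruskal_p` and a data.frame
#'   `welch` (`group1`, `group2`, `p`, `significant`).
#' @export
group_tests <- function(scores, groups, alpha = 0.05, p_adjust = "none") {
  scores <- as.matrix(scores)
  groups <- factor(groups)
  if (any(table(groups) < 3)) stop("need at least 3 subjects per group")
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  comps <- lapply(seq_len(ncol(scores)), function(j) {
    s <- scores[, j]
    for (g in lev) {
      sg <- s[groups == g]
      if (length(sg) < 2 || stats::sd(sg) == 0) {
        if (length(sg) < 2) stop("group with fewer than 2 subjects")
      }
    }
    sw <- stats::shapiro.test(s)$p.value
    kw <- stats::kruskal.test(s, groups)$p.value
    wp <- apply(pairs, 2, function(pr) {
      a <- s[groups == pr[1]]
      b <- s[groups == pr[2]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
        return(1)
      }
      stats::t.test(a, b, var.equal = FALSE)$p.value
    })
    wp_adj <- stats::p.adjust(wp, method = p_adjust)
    list(
      shapiro_p = sw,
      kruskal_p = kw,
      welch = data.frame(
        group1 = pairs[1, ], group2 = pairs[2, ],
        p = wp_adj, significant = wp_adj < alpha
      )
    )
  })
  names(comps) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(components = comps, alpha = alpha, p_adjust = p_adjust),
            class = "group_test_report")
}

#' @export
print.group_test_report <- function(x, ...) {
  for (nm in names(x$components)) {
    comp <- x$components[[nm]]
    cat(sprintf("%s: Shapiro-Wilk p = %.4g, Kruskal-Wallis p = %.4g\n",
                nm, comp$shapiro_p, comp$kruskal_p))
    for (i in seq_len(nrow(comp$welch))) {
      cat(sprintf("  Welch %s vs %s: p = %.4g%s\n",
                  comp$welch$group1[i], comp$welch$group2[i], comp$welch$p[i],
                  if (comp$welch$significant[i]) " *" else ""))
    }
  }
  invisible(x)
}
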