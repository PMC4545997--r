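#' Metabolic divergence versus divergence time, in 20-My bins
#'
#' For each role subnetwork and each patristic-distance bin (half-open
#' windows `[0, w)`, `[w, 2w)`, ... My), regresses pairwise metabolic
#' distance on patristic distance and reports the standardized slope b_ST
#' (the Pearson correlation, i.e. the slope in SD units) with a nominal
#' two-sided test. Species pairs are not phylogenetically independent, so
#' p-values are nominal. An overall Spearman rank correlation across all
#' pairs is returned per role.
#'
#' @param dist_by_role named list of metabolic distance matrices (e.g. from
#'   [pairwise_matrix()] with each role filter; use name `"all"` for the
#'   unfiltered matrix).
#' @param tree dated `phylo` tree whose tips match the matrix dimnames.
#' @param bin_width bin width in My (default 20).
#' @param min_pairs minimum pairs per bin; smaller bins are skipped.
#' @return list with `bins` (role, bin_lo, bin_hi, n_pairs, b_st, p) and
#'   `overall` (role, spearman_r, p, n_pairs).
#' @export
divergence_time_regression <- function(dist_by_role, tree, bin_width = 20,
                                       min_pairs = 3L) {
  pm <- patristic_matrix(tree)
  bins <- NULL
  overall <- NULL
  for (role in names(dist_by_role)) {
    d <- dist_by_role[[role]]
    sp <- intersect(rownames(d), rownames(pm))
    idx <- t(combn(sp, 2L))
    met <- d[idx]
    pat <- pm[idx]
    ok <- !is.na(met)
    met <- met[ok]; pat <- pat[ok]
    if (length(met) >= 3L) {
      st <- suppressWarnings(stats::cor.test(pat, met, method = "spearman",
                                             exact = FALSE))
      overall <- rbind(overall, data.frame(
        role = role, spearman_r = unname(st$estimate), p = st$p.value,
        n_pairs = length(met), stringsAsFactors = FALSE))
    }
    lo <- 0
    while (lo < max(pat)) {
      hi <- lo + bin_width
      in_bin <- pat >= lo & pat < hi
      if (sum(in_bin) >= min_pairs) {
        x <- pat[in_bin]; y <- met[in_bin]
        if (sd(x) > 0 && sd(y) > 0) {
          b_st <- cor(x, y)
          n <- length(x)
          tval <- b_st * sqrt((n - 2) / max(1 - b_st^2, .Machine$double.eps))
          p <- 2 * pt(-abs(tval), df = n - 2)
        } else {
          b_st <- NA_real_; p <- NA_real_
        }
        bins <- rbind(bins, data.frame(
          role = role, bin_lo = lo, bin_hi = hi, n_pairs = sum(in_bin),
          b_st = b_st, p = p, stringsAsFactors = FALSE))
      }
      lo <- hi
    }
  }
  list(bins = bins, overall = overall)
}

#' Phylogenetic independent contrasts regression
#'
#' Felsenstein contrasts for x and y (node-wise differences scaled by the
#' square root of summed branch lengths), then regression through the
#' origin. Polytomies are resolved arbitrarily with zero-length edges, and
#' zero-length edges are replaced by a small epsilon so contrast scaling
#' stays defined (both steps are reported via messages).
#'
#' @param tree `phylo` tree.
#' @param x,y named numeric vectors of tip values (names = tip labels).
#' @param eps branch-length floor substituted for zero-length edges (My).
#' @return list with `slope`, `b_st` (correlation through the origin),
#'   `p`, `n_contrasts`, and the contrast vectors.
#' @export
contrasts_regression <- function(tree, x, y, eps = 1e-8) {
  if (!ape::is.binary(tree)) {
    message("resolving polytomies with zero-length edges")
    tree <- ape::multi2di(tree)
  }
  if (any(tree$edge.length <= 0)) {
    message("substituting epsilon for ", sum(tree$edge.length <= 0),
            " non-positive branch length(s)")
    tree$edge.length[tree$edge.length <= 0] <- eps
  }
  x <- x[tree$tip.label]
  y <- y[tree$tip.label]
  if (anyNA(x) || anyNA(y)) stop("tip data incomplete")
  cx <- ape::pic(x, tree)
  cy <- ape::pic(y, tree)
  fit <- lm(cy ~ cx - 1)
  b_st <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  p <- summary(fit)$coefficients[1, 4]
  list(slope = unname(coef(fit)[1]), b_st = b_st, p = p,
       n_contrasts = length(cx), contrasts_x = cx, contrasts_y = cy)
}

#' One-way test of metabolic elongation against dietary breadth
#'
#' Groups species by whether they utilise more than two distinct dietary
#' carotenoids and tests equality of mean longest elongation with a
#' one-way F on (1, N - 2) degrees of freedom.
#'
#' @param species_table data.frame with columns `n_dietary` and
#'   `elongation`.
#' @param threshold dietary-compound count splitting the groups (default 2:
#'   groups are <= 2 versus > 2).
#' @return list with `F`, `df1`, `df2`, `p`, and per-group means/sizes.
#' @export
elongation_vs_diet_groups <- function(species_table, threshold = 2L) {
  grp <- factor(ifelse(species_table$n_dietary > threshold, "gt", "le"),
                levels = c("le", "gt"))
  if (any(table(grp) == 0L)) stop("a dietary-breadth group is empty")
  if (any(table(grp) < 2L)) stop("need at least two species per group")
  fit <- lm(species_table$elongation ~ grp)
  an <- anova(fit)
  list(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2],
       p = an$`Pr(>F)`[1],
       group_means = tapply(species_table$elongation, grp, mean),
       group_sizes = as.integer(table(grp)))
}
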