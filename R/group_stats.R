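# Per-animal summarization and the named group-comparison tests applied to
# every module's outputs. The tests themselves are vetted library routines;
# this module encodes the dispatch — which test for which readout — and the
# adjustment conventions.

#' Per-animal averages from per-field-of-view records
#'
#' Counts are averaged over all fields of view (FOV) of all sections of each
#' animal with a plain mean (5 FOV across at least three sections in the
#' emulated design); the number of sections and FOVs entering each average is
#' reported for audit, and unbalanced designs are flagged rather than
#' reweighted.
#'
#' @param records data frame with columns `animal`, `group`, `section`,
#'   `fov`, `value` (one row per FOV measurement).
#' @return Data frame with one row per animal: `animal`, `group`, `value`
#'   (the per-animal mean), `n_sections`, `n_fov`, `balanced`.
#' @export
per_animal_summary <- function(records) {
  need <- c("animal", "group", "section", "fov", "value")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  sp <- split(records, records$animal)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(animal = d$animal[1], group = d$group[1],
               value = mean(d$value),
               n_sections = length(unique(d$section)), n_fov = nrow(d))
  }))
  out$balanced <- length(unique(out$n_fov)) == 1
  rownames(out) <- NULL
  out[order(out$group, out$animal), ]
}

# Holm-Sidak step-down adjustment of a vector of p-values.
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m); out[o] <- adj
  out
}

#' Group comparison with the study's named tests
#'
#' One entry point dispatching to the statistical test used for each readout:
#' \describe{
#'   \item{`welch_t`}{unpaired Welch's t-test on per-animal values (two
#'     groups; columns `group`, `value`).}
#'   \item{`mann_whitney_u`}{two-sample Wilcoxon rank-sum / Mann-Whitney U
#'     (columns `group`, `value`).}
#'   \item{`anova2_holm_sidak`}{two-way ANOVA (`value ~ group * factor2`,
#'     the second factor named by `factor2`) with post-hoc per-level group
#'     comparisons adjusted by Holm-Sidak step-down.}
#'   \item{`chi2_distributions`}{Pearson chi-square comparison of binned
#'     count distributions (`data` = groups x bins count matrix).}
#'   \item{`kruskal_fdr`}{Kruskal-Wallis per feature (columns `group`,
#'     `value`, optional `feature`) with Benjamini-Hochberg adjustment across
#'     features.}
#'   \item{`one_sample_t`}{two-tailed one-sample t-test of `value` against
#'     `mu` (default 0, i.e. assuming no expression).}
#'   \item{`ordinal_shift_chi2`}{r x c chi-square on an ordinal score by
#'     group contingency (columns `group`, `score`); `trend = TRUE` uses a
#'     Cochran-Armitage-style score test of trend instead (two groups).}
#' }
#'
#' @param data data frame (or count matrix for `chi2_distributions`) as
#'   described per method.
#' @param method one of the method names above.
#' @param mu null value for `one_sample_t`.
#' @param factor2 column name of the second factor for `anova2_holm_sidak`
#'   (default `"region"`).
#' @param trend use the trend variant of `ordinal_shift_chi2`.
#' @param alpha decision threshold, default 0.05.
#' @return Tidy data frame: `method`, `term`, `statistic`, `p`, `adj_p`,
#'   `n`, `alpha`, `reject` (based on `adj_p`). The first row is the primary
#'   comparison.
#' @export
compare_groups <- function(data,
                           method = c("welch_t", "mann_whitney_u",
                                      "anova2_holm_sidak",
                                      "chi2_distributions", "kruskal_fdr",
                                      "one_sample_t", "ordinal_shift_chi2"),
                           mu = 0, factor2 = "region", trend = FALSE,
                           alpha = 0.05) {
  method <- match.arg(method)
  row <- function(term, statistic, p, n, adj_p = p)
    data.frame(method = method, term = term, statistic = statistic, p = p,
               adj_p = adj_p, n = n, alpha = alpha, reject = adj_p < alpha)
  two_groups <- function(d) {
    g <- unique(as.character(d$group))
    if (length(g) != 2) stop(method, " needs exactly two groups")
    if (min(table(d$group)) < 2) stop("group sizes must be >= 2")
    g
  }
  out <- switch(method,
    welch_t = {
      g <- two_groups(data)
      tt <- stats::t.test(value ~ group, data = data, var.equal = FALSE)
      row(paste(g, collapse = " vs "), unname(tt$statistic), tt$p.value, nrow(data))
    },
    mann_whitney_u = {
      g <- two_groups(data)
      wt <- suppressWarnings(stats::wilcox.test(value ~ group, data = data))
      row(paste(g, collapse = " vs "), unname(wt$statistic), wt$p.value, nrow(data))
    },
    anova2_holm_sidak = {
      if (!factor2 %in% names(data)) stop("missing second factor column: ", factor2)
      d <- data; d$.f2 <- factor(d[[factor2]]); d$group <- factor(d$group)
      fit <- stats::aov(value ~ group * .f2, data = d)
      sm <- summary(fit)[[1]]
      rownames(sm) <- trimws(rownames(sm))
      main <- row("group", sm["group", "F value"], sm["group", "Pr(>F)"], nrow(d))
      inter <- row("group:" %+% factor2, sm["group:.f2", "F value"],
                   sm["group:.f2", "Pr(>F)"], nrow(d))
      lev <- levels(d$.f2)
      post <- lapply(lev, function(l) {
        dd <- d[d$.f2 == l, ]
        tt <- stats::t.test(value ~ group, data = dd, var.equal = FALSE)
        row(factor2 %+% "=" %+% l, unname(tt$statistic), tt$p.value, nrow(dd))
      })
      post <- do.call(rbind, post)
      post$adj_p <- holm_sidak(post$p)
      post$reject <- post$adj_p < alpha
      rbind(main, inter, post)
    },
    chi2_distributions = {
      tab <- as.matrix(data)
      ct <- suppressWarnings(stats::chisq.test(tab))
      row("distribution", unname(ct$statistic), ct$p.value, sum(tab))
    },
    kruskal_fdr = {
      if (is.null(data$feature)) data$feature <- "value"
      sp <- split(data, data$feature)
      res <- do.call(rbind, lapply(sp, function(d) {
        kt <- stats::kruskal.test(value ~ factor(group), data = d)
        row(d$feature[1], unname(kt$statistic), kt$p.value, nrow(d))
      }))
      res$adj_p <- stats::p.adjust(res$p, "BH")
      res$reject <- res$adj_p < alpha
      rownames(res) <- NULL
      res
    },
    one_sample_t = {
      tt <- stats::t.test(data$value, mu = mu)
      row(sprintf("mu=%g", mu), unname(tt$statistic), tt$p.value, nrow(data))
    },
    ordinal_shift_chi2 = {
      if (is.null(data$score)) stop("ordinal_shift_chi2 needs a 'score' column")
      if (!is.numeric(data$score) && !is.ordered(data$score))
        stop("ordinal scores must be numeric or ordered factors")
      if (length(unique(data$score)) > 12)
        stop("scores have too many distinct values to be ordinal grades; ",
             "use a continuous-data test instead")
      tab <- table(data$group, data$score)
      if (trend) {
        if (nrow(tab) != 2) stop("trend variant needs exactly two groups")
        sc <- as.numeric(colnames(tab))
        pt <- stats::prop.trend.test(tab[2, ], colSums(tab), score = sc)
        row("ordinal trend", unname(pt$statistic), pt$p.value, sum(tab))
      } else {
        ct <- suppressWarnings(stats::chisq.test(tab))
        row("ordinal shift", unname(ct$statistic), ct$p.value, sum(tab))
      }
    })
  rownames(out) <- NULL
  out
}

`%+%` <- function(a, b) paste0(a, b)

#' Default test for each pipeline readout
#'
#' Encodes which named test is applied to which quantification by default:
#' per-animal FOV summaries (cell fractions, cells per mm) use Welch's t;
#' ultrastructure (g-ratio and friends) and bootstrap lesion volumes use
#' Mann-Whitney U; lesion core/edge cell counts use two-way ANOVA with
#' Holm-Sidak post hocs; radial myelination profiles use the chi-square
#' comparison of distributions; conditioned-media analyte panels use
#' Kruskal-Wallis with FDR correction; expression-versus-zero readouts use
#' the one-sample t; ordinal severity scores use the ordinal shift
#' chi-square.
#'
#' @param readout one of `"fov_summary"`, `"ultrastructure"`,
#'   `"lesion_volume"`, `"core_edge_counts"`, `"myelination_profile"`,
#'   `"analyte_panel"`, `"expression_vs_zero"`, `"ordinal_score"`.
#' @return The method name accepted by [compare_groups()].
#' @export
default_test_for <- function(readout) {
  map <- c(fov_summary = "welch_t",
           ultrastructure = "mann_whitney_u",
           lesion_volume = "mann_whitney_u",
           core_edge_counts = "anova2_holm_sidak",
           myelination_profile = "chi2_distributions",
           analyte_panel = "kruskal_fdr",
           expression_vs_zero = "one_sample_t",
           ordinal_score = "ordinal_shift_chi2")
  if (!readout %in% names(map)) stop("unknown readout: ", readout)
  unname(map[readout])
}
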