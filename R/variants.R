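#' Evaluate reading-frame preservation of minor-major links
#'
#' A minor splice variant whose boundary offset from the major boundary is a
#' multiple of 3 leaves the reading frame intact. Frame preservation is only
#' evaluated for offsets within `max_window` bp (the window is kept shorter
#' than the smallest metazoan introns so that no skipped exon can sit
#' between the two splice sites); links with larger offsets get
#' `frame_preserving = NA` (not evaluated).
#'
#' @param links Link table from [link_minor_variants()] (needs `offset`).
#' @param max_window Maximum offset in bp for frame evaluation (default 30,
#'   inclusive).
#' @return `links` with a logical `frame_preserving` column (`NA` when the
#'   offset exceeds `max_window`).
#' @export
link_and_offset <- function(links, max_window = 30L) {
  links <- as.data.frame(links)
  if (any(links$offset == 0L))
    stop("offset 0 would imply identical minor and major introns")
  links$frame_preserving <- ifelse(links$offset <= max_window,
                                   links$offset %% 3L == 0L, NA)
  links
}

#' MIRA profile of frame preservation
#'
#' Bins minor variants by their MIRA (minor intron relative abundance) into
#' 20 contiguous 5%-wide bins spanning (0, 1] (or equal-count quantile bins)
#' and reports, per bin, the number of variants and the proportion of
#' frame-preserving events among those evaluated.
#'
#' @param links Link table with `MIRA` and `frame_preserving` (from
#'   [quantify_major_introns()] + [link_and_offset()]).
#' @param n_bins Number of bins (default 20).
#' @param equal_count If `TRUE`, use equal-count (quantile) bins instead of
#'   fixed-width bins.
#' @return A data.frame with `bin_index`, `bin_low`, `bin_high`,
#'   `n_variants`, `n_evaluated`, `prop_frame_preserving` (`NA` for empty
#'   bins).
#' @export
mira_profile <- function(links, n_bins = 20L, equal_count = FALSE) {
  links <- as.data.frame(links)
  stopifnot(all(!is.na(links$MIRA)))
  if (equal_count) {
    br <- unique(quantile(links$MIRA, probs = seq(0, 1, length.out =
                                                    n_bins + 1L)))
    br[1L] <- 0
    br[length(br)] <- max(1, br[length(br)])
  } else {
    br <- seq(0, 1, length.out = n_bins + 1L)
  }
  bin <- cut(links$MIRA, breaks = br, include.lowest = FALSE, right = TRUE)
  nb <- length(br) - 1L
  n_var <- as.integer(table(bin))
  ev <- !is.na(links$frame_preserving)
  n_ev <- as.integer(table(bin[ev]))
  n_fp <- as.integer(table(bin[ev & links$frame_preserving]))
  data.frame(
    bin_index = seq_len(nb),
    bin_low = br[-length(br)],
    bin_high = br[-1L],
    n_variants = n_var,
    n_evaluated = n_ev,
    prop_frame_preserving = ifelse(n_ev > 0L, n_fp / n_ev, NA_real_))
}

#' Split splice variants into abundant and rare
#'
#' Abundant splice variants have `MIRA > threshold` (strict); rare ones have
#' `MIRA <= threshold`.
#'
#' @param mira Numeric vector of MIRA values.
#' @param threshold Abundance threshold (default 0.05).
#' @return Character vector, `"abundant"` or `"rare"`.
#' @export
split_abundant_rare <- function(mira, threshold = 0.05) {
  stopifnot(all(!is.na(mira)))
  ifelse(mira > threshold, "abundant", "rare")
}

#' Categorize major introns by splice-variant abundance
#'
#' A major-isoform intron is `high_AS` when at least one of its linked minor
#' variants is abundant (`MIRA > threshold`); otherwise (including introns
#' with no variant at all) it is `low_AS`.
#'
#' @param majors Major-intron table from [quantify_major_introns()].
#' @param links Link table with `MIRA` and `major_row`.
#' @param threshold Abundance threshold (default 0.05).
#' @return `majors` with a character `category` column
#'   (`"low_AS"`/`"high_AS"`).
#' @export
categorize_major_introns <- function(majors, links, threshold = 0.05) {
  majors <- as.data.frame(majors)
  majors$category <- "low_AS"
  if (nrow(links)) {
    hi <- unique(links$major_row[links$MIRA > threshold])
    rowid <- if (!is.null(majors$major_id)) majors$major_id else
      seq_len(nrow(majors))
    majors$category[rowid %in% hi] <- "high_AS"
  }
  majors
}

#' Frame-preservation enrichment of abundant vs rare variants
#'
#' Compares the proportion of frame-preserving events among abundant splice
#' variants with that among rare ones. Either pass the two proportions
#' directly, or pass a link table (with `MIRA` and `frame_preserving`) from
#' which both proportions are computed over evaluated links.
#'
#' @param abundant Either the abundant-class proportion (numeric scalar) or
#'   a link table.
#' @param rare The rare-class proportion (ignored when `abundant` is a
#'   table).
#' @param threshold MIRA threshold used when computing from a link table.
#' @param statistic `"ratio"` (abundant / rare, default) or `"odds_ratio"`.
#' @return The enrichment statistic (`NA` with a warning if the rare-class
#'   proportion is 0 for the ratio form).
#' @export
frame_enrichment <- function(abundant, rare = NULL, threshold = 0.05,
                             statistic = c("ratio", "odds_ratio")) {
  statistic <- match.arg(statistic)
  if (is.data.frame(abundant)) {
    links <- abundant[!is.na(abundant$frame_preserving), , drop = FALSE]
    grp <- split_abundant_rare(links$MIRA, threshold)
    if (!any(grp == "abundant") || !any(grp == "rare"))
      stop("need at least one evaluated variant in each abundance class")
    abundant <- mean(links$frame_preserving[grp == "abundant"])
    rare <- mean(links$frame_preserving[grp == "rare"])
  }
  stopifnot(is.numeric(abundant), is.numeric(rare))
  if (statistic == "odds_ratio") {
    return((abundant / (1 - abundant)) / (rare / (1 - rare)))
  }
  if (rare == 0) {
    warning("rare-class proportion is 0; ratio enrichment undefined")
    return(NA_real_)
  }
  abundant / rare
}

#' Correlation between gene expression and per-intron AS rate
#'
#' Restricts to major introns measured precisely enough
#' (`Ns + Na >= min_reads`), sorts them by gene expression, forms
#' `n_bins` equal-count bins, and correlates (Pearson) the per-bin mean AS
#' rate with the per-bin median expression.
#'
#' @param majors Major-intron table with `AS`, `Ns`, `Na` and an expression
#'   column.
#' @param expression Name of the expression column (default
#'   `"expression"`).
#' @param min_reads Minimum `Ns + Na` (default 100).
#' @param n_bins Number of expression bins (default 20).
#' @param log_expression If `TRUE`, correlate against log10 median
#'   expression.
#' @return A list with `r` (Pearson correlation across bins), `p_value`
#'   (two-sided), `n_introns` and `bins` (a data.frame with `bin_index`,
#'   `median_expression`, `mean_AS`, `n_introns`). `r` is `NA` with a
#'   warning when a binned vector has zero variance.
#' @export
expression_as_correlation <- function(majors, expression = "expression",
                                      min_reads = 100L, n_bins = 20L,
                                      log_expression = FALSE) {
  majors <- as.data.frame(majors)
  x <- majors[[expression]]
  keep <- majors$Ns + majors$Na >= min_reads & !is.na(majors$AS) & !is.na(x)
  d <- majors[keep, , drop = FALSE]
  x <- x[keep]
  if (nrow(d) < n_bins)
    stop("fewer filtered introns (", nrow(d), ") than bins (", n_bins, ")")
  ord <- order(x)
  d <- d[ord, , drop = FALSE]
  x <- x[ord]
  bin <- ceiling(seq_along(x) * n_bins / length(x))
  bins <- data.frame(
    bin_index = seq_len(n_bins),
    median_expression = as.numeric(tapply(x, bin, median)),
    mean_AS = as.numeric(tapply(d$AS, bin, mean)),
    n_introns = as.integer(table(bin)))
  bx <- if (log_expression) log10(bins$median_expression) else
    bins$median_expression
  if (sd(bx) == 0 || sd(bins$mean_AS) == 0) {
    warning("zero variance across bins; correlation undefined")
    return(list(r = NA_real_, p_value = NA_real_, n_introns = nrow(d),
                bins = bins))
  }
  ct <- cor.test(bx, bins$mean_AS, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n_introns = nrow(d),
       bins = bins)
}
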