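# Targeted-metabolomics index statistics. All comparisons are two-group,
# unpaired, two-sided Student (equal-variance) t-tests with Benjamini-
# Hochberg correction within an analysis family. Ratios are computed within
# each sample before any group summarization (intra-sample ratios), which
# cancels per-sample scaling factors such as cell-number normalization.

#' Construct a metabolite abundance table
#'
#' @param abundances metabolites x samples numeric matrix (non-negative,
#'   absolute units such as pmol per 1e6 cells) with metabolite rownames and
#'   sample colnames.
#' @param groups factor or character vector of group labels, one per sample
#'   (exactly two levels for inferential operations).
#' @return A `metabolite_table` object.
#' @export
metabolite_table <- function(abundances, groups) {
  abundances <- as.matrix(abundances)
  storage.mode(abundances) <- "double"
  if (is.null(rownames(abundances))) stop("abundance matrix needs metabolite rownames")
  if (any(is.na(abundances))) stop("NA abundances are not allowed")
  if (any(abundances < 0)) stop("abundances must be non-negative")
  if (length(groups) != ncol(abundances)) {
    stop("one group label per sample is required")
  }
  groups <- as.character(groups)
  structure(list(abundances = abundances, groups = groups),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("<metabolite_table> %d metabolites x %d samples; groups: %s\n",
              nrow(x$abundances), ncol(x$abundances),
              paste(sprintf("%s (n=%d)", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

two_groups <- function(table) {
  lv <- unique(table$groups)
  if (length(lv) != 2) stop("exactly two groups are required, got: ",
                            paste(lv, collapse = ", "))
  if (any(table(table$groups) < 2)) stop("each group needs >= 2 samples")
  lv
}

student_t <- function(x, y) {
  # degenerate inputs (zero pooled variance, non-finite indices) get NA/0
  # rather than an abort, so one flat ratio cannot sink a whole panel
  if (any(!is.finite(c(x, y)))) return(c(t = NA_real_, p = NA_real_))
  if (var(x) + var(y) <= 0) {
    d <- mean(x) - mean(y)
    if (d == 0) return(c(t = NA_real_, p = NA_real_))
    return(c(t = sign(d) * Inf, p = 0))
  }
  tt <- t.test(x, y, var.equal = TRUE, alternative = "two.sided")
  c(t = unname(tt$statistic), p = tt$p.value)
}

bh_with_na <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) q[ok] <- bh_adjust(p[ok])
  q
}

#' Intra-sample ratio of two metabolites
#'
#' Computes `numerator / denominator` within each sample, then summarizes per
#' group (mean +/- SD) and tests the group difference with an unpaired
#' two-sided Student t-test. Set `log_ratios = TRUE` to test on the log scale
#' instead of raw ratios.
#'
#' @param table a `metabolite_table` with two groups.
#' @param numerator_id,denominator_id metabolite row ids.
#' @param log_ratios test log-transformed ratios (default `FALSE`: raw).
#' @return A `ratio_stat` list: per-sample `ratios`, per-group `mean` and
#'   `sd`, `t`, `p`. The `q` slot is `NA` until the ratio is adjusted within
#'   a family via [bh_adjust()].
#' @export
intra_sample_ratio <- function(table, numerator_id, denominator_id,
                               log_ratios = FALSE) {
  stopifnot(inherits(table, "metabolite_table"))
  lv <- two_groups(table)
  ab <- table$abundances
  for (id in c(numerator_id, denominator_id)) {
    if (!(id %in% rownames(ab))) stop("metabolite not in table: ", id)
  }
  den <- ab[denominator_id, ]
  zero <- which(den <= 0)
  if (length(zero)) {
    stop("zero denominator (", denominator_id, ") in sample ",
         colnames(ab)[zero[1]])
  }
  ratios <- ab[numerator_id, ] / den
  val <- if (log_ratios) log(ratios) else ratios
  g1 <- val[table$groups == lv[1]]; g2 <- val[table$groups == lv[2]]
  tt <- student_t(g1, g2)
  structure(list(
    numerator = numerator_id, denominator = denominator_id,
    ratios = ratios, groups = table$groups, log_ratios = log_ratios,
    mean = setNames(c(mean(g1), mean(g2)), lv),
    sd = setNames(c(sd(g1), sd(g2)), lv),
    t = tt[["t"]], p = tt[["p"]], q = NA_real_), class = "ratio_stat")
}

#' @export
print.ratio_stat <- function(x, ...) {
  cat(sprintf("<ratio_stat> %s / %s%s\n", x$numerator, x$denominator,
              if (x$log_ratios) " (log scale)" else ""))
  for (g in names(x$mean)) {
    cat(sprintf("  %s: %.4g +/- %.4g\n", g, x$mean[[g]], x$sd[[g]]))
  }
  cat(sprintf("  t = %.3f, p = %.3g, q = %s\n", x$t, x$p, format(x$q)))
  invisible(x)
}

#' Adenylate energy-state indices
#'
#' Per-sample adenylate energy charge `(ATP + 0.5 ADP) / (ATP + ADP + AMP)`
#' (the Atkinson index, in [0, 1]), AMP fraction `AMP / (AMP + ADP + ATP)`,
#' and `ATP/ADP` ratio, with group summaries and Student t-tests corrected
#' across the three indices by Benjamini-Hochberg.
#'
#' @param table a `metabolite_table` containing rows named by `amp_id`,
#'   `adp_id`, `atp_id`.
#' @param amp_id,adp_id,atp_id row ids of the adenylates (defaults `"AMP"`,
#'   `"ADP"`, `"ATP"`).
#' @return list with `per_sample` (index x sample matrix), `summary`
#'   (data.frame: index, group means/SDs, `t`, `p`, `q`), and `groups`.
#' @export
adenylate_indices <- function(table, amp_id = "AMP", adp_id = "ADP",
                              atp_id = "ATP") {
  stopifnot(inherits(table, "metabolite_table"))
  lv <- two_groups(table)
  ab <- table$abundances
  for (id in c(amp_id, adp_id, atp_id)) {
    if (!(id %in% rownames(ab))) stop("metabolite not in table: ", id)
  }
  amp <- ab[amp_id, ]; adp <- ab[adp_id, ]; atp <- ab[atp_id, ]
  pool <- amp + adp + atp
  if (any(pool <= 0)) {
    stop("all-zero adenylate pool in sample ", colnames(ab)[which(pool <= 0)[1]])
  }
  per_sample <- rbind(
    energy_charge = (atp + 0.5 * adp) / pool,
    amp_fraction = amp / pool,
    atp_adp_ratio = ifelse(adp > 0, atp / adp, Inf))
  rows <- lapply(rownames(per_sample), function(idx) {
    v <- per_sample[idx, ]
    g1 <- v[table$groups == lv[1]]; g2 <- v[table$groups == lv[2]]
    tt <- student_t(g1, g2)
    data.frame(index = idx,
               mean_1 = mean(g1), sd_1 = sd(g1),
               mean_2 = mean(g2), sd_2 = sd(g2),
               t = tt[["t"]], p = tt[["p"]], stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  names(summary)[2:5] <- c(paste0("mean_", lv[1]), paste0("sd_", lv[1]),
                           paste0("mean_", lv[2]), paste0("sd_", lv[2]))
  summary$q <- bh_with_na(summary$p)
  list(per_sample = per_sample, summary = summary, groups = table$groups)
}

#' Per-metabolite fold changes between the two groups
#'
#' Ratio of group means, `mean(numerator group) / mean(denominator group)`.
#' Metabolites whose denominator-group mean is zero are flagged `undefined`
#' rather than silently dropped.
#'
#' @param table a `metabolite_table` with two groups.
#' @param numerator_group group label used as the numerator; defaults to the
#'   first label encountered.
#' @return data.frame with `metabolite`, `fold_change`, `undefined`.
#' @export
fold_changes <- function(table, numerator_group = NULL) {
  stopifnot(inherits(table, "metabolite_table"))
  lv <- two_groups(table)
  if (is.null(numerator_group)) numerator_group <- lv[1]
  if (!(numerator_group %in% lv)) stop("unknown group: ", numerator_group)
  den_group <- setdiff(lv, numerator_group)
  num_mean <- rowMeans(table$abundances[, table$groups == numerator_group, drop = FALSE])
  den_mean <- rowMeans(table$abundances[, table$groups == den_group, drop = FALSE])
  undef <- den_mean <= 0
  fc <- ifelse(undef, NA_real_, num_mean / den_mean)
  data.frame(metabolite = rownames(table$abundances), fold_change = fc,
             undefined = undef, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment
#' (`q(i) = min over j >= i of p(j) * m / j` on the sorted p-values). The
#' returned values satisfy `p <= q <= 1` and preserve ties.
#'
#' @param p_values numeric vector in [0, 1].
#' @return Vector of q-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Pi-value gene-ranking score
#'
#' Combined effect-size/significance score `lfc * (-log10 p)` used to
#' pre-rank genes for enrichment analysis. The sign follows the log fold
#' change; for fixed positive `lfc` the score decreases monotonically in `p`.
#'
#' @param lfc log2 fold change(s).
#' @param p p-value(s) in (0, 1]; `p = 0` is an error (infinite score) — the
#'   caller must floor p-values first.
#' @return Numeric score vector.
#' @export
pi_value_rank <- function(lfc, p) {
  if (length(lfc) != length(p)) stop("lfc and p must have equal length")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]; floor zero p-values before ranking")
  }
  lfc * (-log10(p))
}
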