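## concordance: the analysis core. Classify every (site, sample) triple of
## platform calls by alternate-allele positivity and summarise per sample and
## across samples.

#' Call tensor: sites x samples x platforms genotype store
#'
#' The pipeline's central structure. States are integers (0 hom-ref, 1 het,
#' 2 hom-alt, NA missing); depth is an optional parallel array (arrays have
#' no depth).
#'
#' @param panel a [site_panel].
#' @param states named list of sites x samples integer matrices, one per
#'   platform.
#' @param depths optional named list of depth matrices (subset of platforms).
#' @param roles named character vector mapping roles
#'   (`array_reference`, `wgs`, `exome`) to platform labels.
#' @return object of class `call_tensor`.
#' @export
call_tensor <- function(panel, states, depths = NULL,
                        roles = c(array_reference = "array", wgs = "wgs",
                                  exome = "exome")) {
  platforms <- names(states)
  if (is.null(platforms)) stop("states must be a named list of matrices")
  samples <- colnames(states[[1]])
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(states[[1]])))
  for (p in platforms) {
    if (!all(dim(states[[p]]) == c(nrow(panel), length(samples))))
      stopf("platform '%s': state matrix dims do not match panel x samples", p)
  }
  if (!all(roles %in% platforms))
    stop("roles must name platforms present in the tensor")
  if (sum(names(roles) == "array_reference") != 1L)
    stop("exactly one platform must be tagged array_reference")
  arr <- array(NA_integer_,
               dim = c(nrow(panel), length(samples), length(platforms)),
               dimnames = list(NULL, samples, platforms))
  dep <- array(NA_integer_, dim = dim(arr), dimnames = dimnames(arr))
  for (p in platforms) {
    arr[, , p] <- as.integer(states[[p]])
    if (!is.null(depths[[p]])) dep[, , p] <- as.integer(depths[[p]])
  }
  structure(list(panel = panel, samples = samples, platforms = platforms,
                 roles = roles, state = arr, depth = dep),
            class = "call_tensor")
}

#' @export
print.call_tensor <- function(x, ...) {
  cat(sprintf("<call_tensor> %d sites x %d samples x %d platforms (%s)\n",
              nrow(x$panel), length(x$samples), length(x$platforms),
              paste(x$platforms, collapse = ", ")))
  invisible(x)
}

role_platform <- function(tensor, role) unname(tensor$roles[[role]])

check_platform <- function(tensor, platform) {
  if (!platform %in% tensor$platforms)
    stopf("unknown platform '%s' (tensor has: %s)", platform,
          paste(tensor$platforms, collapse = ", "))
  platform
}

#' Alternate-allele positivity
#'
#' A call is alt-positive iff it carries at least one non-reference allele
#' (het or hom-alt), regardless of allelic state. MISSING is not alt-positive;
#' callers track missingness separately via `is.na()`.
#'
#' @param state integer genotype state vector/matrix.
#' @return logical of the same shape.
#' @export
alt_positive <- function(state) !is.na(state) & state >= GT_HET

## slice one platform out of a sites x samples x platforms array without
## ever dropping the first two dimensions (single-site / single-sample safe)
platform_slice <- function(arr3, platform) {
  i <- match(platform, dimnames(arr3)[[3]])
  m <- arr3[, , i, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  colnames(m) <- dimnames(arr3)[[2]]
  m
}

## alt-positivity matrices for one platform: sites x samples
platform_pos <- function(tensor, platform) {
  alt_positive(platform_slice(tensor$state, check_platform(tensor, platform)))
}
platform_missing <- function(tensor, platform) {
  is.na(platform_slice(tensor$state, check_platform(tensor, platform)))
}

#' Venn classification of calls at each (site, sample)
#'
#' Classifies by which platforms are alt-positive: `OHP` (all three), `OH`,
#' `OP`, `HP` (exactly that pair), `O`, `H`, `P` (exactly one), `NONE`
#' (no platform alt-positive). `O` is the array-reference platform, `H` the
#' WGS platform, `P` the exome platform. A parallel logical marks whether any
#' platform was MISSING at the pair.
#'
#' @param tensor a [call_tensor].
#' @param sample sample label or index.
#' @return data.table with columns `site` (panel row), `class`,
#'   `missing_involved`.
#' @export
classify_venn <- function(tensor, sample) {
  o <- platform_pos(tensor, role_platform(tensor, "array_reference"))[, sample]
  h <- platform_pos(tensor, role_platform(tensor, "wgs"))[, sample]
  p <- platform_pos(tensor, role_platform(tensor, "exome"))[, sample]
  mis <- platform_missing(tensor, role_platform(tensor, "array_reference"))[, sample] |
    platform_missing(tensor, role_platform(tensor, "wgs"))[, sample] |
    platform_missing(tensor, role_platform(tensor, "exome"))[, sample]
  lab <- c("NONE", "P", "H", "HP", "O", "OP", "OH", "OHP")
  cls <- lab[1L + 4L * o + 2L * h + p]
  data.table(site = seq_along(cls), class = cls, missing_involved = mis)
}

#' Per-sample Venn class counts
#'
#' @inheritParams classify_venn
#' @return named integer vector over the 8 classes (sums to panel size).
#' @export
venn_counts <- function(tensor, sample) {
  cls <- classify_venn(tensor, sample)$class
  lab <- c("OHP", "OH", "OP", "HP", "O", "H", "P", "NONE")
  vapply(lab, function(l) sum(cls == l), integer(1))
}

#' Per-sample concordance summary (one summary-table row)
#'
#' Counts alt-positive calls per platform, pairwise concordant counts
#' (both platforms alt-positive; these INCLUDE the triple overlap), the
#' three-way concordant count, the union of alt-positive sites over the
#' three platforms, and the exome-support ratio
#' `proton_support = all_concordant / ho_concordant`.
#'
#' @inheritParams classify_venn
#' @return one-row data.table: `sample`, `total_calls`, `n_omni`, `n_hiseq`,
#'   `n_proton`, `all_concordant`, `ho_concordant`, `hp_concordant`,
#'   `op_concordant`, `proton_support`.
#' @export
sample_summary <- function(tensor, sample) {
  o <- platform_pos(tensor, role_platform(tensor, "array_reference"))[, sample]
  h <- platform_pos(tensor, role_platform(tensor, "wgs"))[, sample]
  p <- platform_pos(tensor, role_platform(tensor, "exome"))[, sample]
  smp <- if (is.character(sample)) sample else tensor$samples[sample]
  data.table(sample = smp,
             total_calls = sum(o | h | p),
             n_omni = sum(o), n_hiseq = sum(h), n_proton = sum(p),
             all_concordant = sum(o & h & p),
             ho_concordant = sum(h & o),
             hp_concordant = sum(h & p),
             op_concordant = sum(o & p),
             proton_support = sum(o & h & p) / sum(h & o))
}

#' Full per-sample concordance table with Average and %CV rows
#'
#' @param tensor a [call_tensor].
#' @param sd_type `%CV` convention, see [percent_cv()].
#' @return data.table, one row per sample plus `Average` and `%CV` rows.
#' @export
concordance_table <- function(tensor, sd_type = "population") {
  rows <- rbindlist(lapply(tensor$samples, function(s) sample_summary(tensor, s)))
  num <- names(rows)[-1]
  avg <- c(sample = "Average", as.list(round(colMeans(rows[, ..num]), 3)))
  cv  <- c(sample = "%CV",
           as.list(round(vapply(rows[, ..num], percent_cv, numeric(1),
                                sd_type = sd_type), 2)))
  rbindlist(list(rows, avg, cv), use.names = TRUE)
}

#' Overall concordance between two platforms
#'
#' Fraction of (site, sample) pairs where the two platforms agree on
#' alt-positivity. With `include_negatives = TRUE` the denominator is all
#' pairs and agreement includes jointly alt-negative pairs; otherwise the
#' universe is pairs where at least one platform is alt-positive and
#' agreement means both are. Pairs with MISSING on either side are excluded
#' from the denominator under `missing_policy = "exclude"` (default; the
#' excluded count is returned as attribute `n_missing_pairs`) or counted as
#' disagreements under `"discordant"`.
#'
#' @param tensor a [call_tensor].
#' @param platform,reference_platform platform labels.
#' @param include_negatives count jointly-negative agreements.
#' @param missing_policy `"exclude"` or `"discordant"`.
#' @return fraction in \[0, 1\] with attribute `n_missing_pairs`.
#' @export
overall_concordance <- function(tensor, platform, reference_platform,
                                include_negatives = TRUE,
                                missing_policy = c("exclude", "discordant")) {
  missing_policy <- match.arg(missing_policy)
  a <- platform_pos(tensor, platform)
  b <- platform_pos(tensor, reference_platform)
  mis <- platform_missing(tensor, platform) |
    platform_missing(tensor, reference_platform)
  keep <- if (missing_policy == "exclude") !mis else rep(TRUE, length(mis))
  if (include_negatives) {
    agree <- (a == b) & (if (missing_policy == "discordant") !mis else TRUE)
    denom <- sum(keep)
  } else {
    universe <- (a | b) & keep
    agree <- a & b & keep
    denom <- sum(universe)
  }
  val <- if (denom == 0) NA_real_ else sum(agree & keep) / denom
  structure(val, n_missing_pairs = sum(mis))
}

#' Alternative-allele-count level matrix for two platforms
#'
#' Per site, the alternative-allele count on a platform is the sum over
#' samples of 1 per het and 2 per hom-alt call (0 otherwise), ranging 0..2n.
#' The level matrix counts sites per (count on A, count on B) cell; with 12
#' samples it is 25 x 25 and the grand total is the panel size.
#'
#' @param tensor a [call_tensor].
#' @param platform_a,platform_b platform labels (rows index A, columns B).
#' @return integer matrix with dimnames `0..2n`.
#' @export
allele_count_matrix <- function(tensor, platform_a, platform_b) {
  cnt <- function(p) {
    st <- platform_slice(tensor$state, check_platform(tensor, p))
    ac <- matrix(0L, nrow(st), ncol(st))
    ac[!is.na(st) & st == GT_HET] <- 1L
    ac[!is.na(st) & st == GT_HOM_ALT] <- 2L
    rowSums(ac)
  }
  n2 <- 2L * length(tensor$samples)
  a <- cnt(platform_a); b <- cnt(platform_b)
  m <- matrix(0L, n2 + 1L, n2 + 1L, dimnames = list(0:n2, 0:n2))
  t <- table(factor(a, levels = 0:n2), factor(b, levels = 0:n2))
  m[] <- as.integer(t)
  m
}

#' Sites discordant with a reference platform in every sample
#'
#' A (site, sample) pair is discordant when the two platforms disagree on
#' alt-positivity (MISSING counts as not alt-positive). Returns the panel row
#' indices of sites discordant in all samples — the commonly discordant
#' (systematic) sites.
#'
#' @inheritParams overall_concordance
#' @return integer vector of panel row indices.
#' @export
common_discordant_sites <- function(tensor, platform, reference_platform) {
  a <- platform_pos(tensor, platform)
  b <- platform_pos(tensor, reference_platform)
  which(rowSums(a != b) == length(tensor$samples))
}

#' Per-sample NGS-vs-array discordance breakdown
#'
#' For each sample, sites where at least one NGS platform disagrees with the
#' array reference on alt-positivity are classified as: exome concordant &
#' WGS discordant, WGS concordant & exome discordant, both NGS discordant
#' (split into NGS platforms agreeing with each other or not). The `Common`
#' row counts sites in each class for every sample.
#'
#' @param tensor a [call_tensor].
#' @return data.table, one row per sample plus `Average`, `%CV`, `Common`.
#' @export
discordance_summary <- function(tensor) {
  o <- platform_pos(tensor, role_platform(tensor, "array_reference"))
  h <- platform_pos(tensor, role_platform(tensor, "wgs"))
  p <- platform_pos(tensor, role_platform(tensor, "exome"))
  hd <- h != o; pd <- p != o
  per <- data.table(sample = tensor$samples,
                    proton_conc_hiseq_disc = colSums(hd & !pd),
                    hiseq_conc_proton_disc = colSums(!hd & pd),
                    both_discordant = colSums(hd & pd),
                    ngs_agree_both_disc = colSums(hd & pd & (h == p)),
                    all_discordant = colSums(hd & pd & (h != p)),
                    total_discordant = colSums(hd | pd))
  num <- names(per)[-1]
  avg <- c(sample = "Average", as.list(round(colMeans(per[, ..num]), 1)))
  cv <- c(sample = "%CV",
          as.list(round(vapply(per[, ..num], function(v)
            if (mean(v) == 0) 0 else percent_cv(v), numeric(1)), 1)))
  ns <- length(tensor$samples)
  common <- c(sample = "Common", as.list(c(
    proton_conc_hiseq_disc = sum(rowSums(hd & !pd) == ns),
    hiseq_conc_proton_disc = sum(rowSums(!hd & pd) == ns),
    both_discordant = sum(rowSums(hd & pd) == ns),
    ngs_agree_both_disc = sum(rowSums(hd & pd & (h == p)) == ns),
    all_discordant = sum(rowSums(hd & pd & (h != p)) == ns),
    total_discordant = sum(rowSums(hd | pd) == ns))))
  rbindlist(list(per, avg, cv, common), use.names = TRUE)
}
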