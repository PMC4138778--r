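## locus_features: per-site QC covariates — GC content in a 101-base window,
## homopolymer length, transition/transversion class — plus depth pulled from
## the call tensor.

#' GC fraction in a window around a site
#'
#' Computes (#G + #C) / window length over positions
#' `[pos - flank, pos + flank]`, clipped to the chromosome; the denominator is
#' the clipped window length. The default flank of 50 gives the 101-base
#' window used for SNP-locus GC annotation.
#'
#' @param ref a [ref_store].
#' @param chrom,pos site coordinates (1-based).
#' @param flank bases on each side.
#' @return fraction in \[0, 1\].
#' @export
gc_content <- function(ref, chrom, pos, flank = 50L) {
  ref_check(ref, chrom, pos)
  w <- ref_window(ref, chrom, pos - flank, pos + flank)
  n <- nchar(w)
  if (n == 0L) return(NA_real_)
  gc <- n - nchar(gsub("[GC]", "", w))
  gc / n
}

#' Homopolymer length at a site
#'
#' The maximum length over: the run of identical reference bases containing
#' the site, and the runs immediately adjacent on each side. With
#' `include_site = FALSE` the site base itself is excluded and only the two
#' flanking runs (extended through the site if they match each other) are
#' considered.
#'
#' @inheritParams gc_content
#' @param include_site include the run containing the site base (default).
#' @param max_scan scan horizon on each side of the site; runs longer than
#'   this are reported truncated (biological homopolymers are far shorter).
#' @return integer length (>= 1 when `include_site = TRUE`).
#' @export
homopolymer_length <- function(ref, chrom, pos, include_site = TRUE,
                               max_scan = 200L) {
  ref_check(ref, chrom, pos)
  chrom <- normalize_chrom(chrom)
  lo <- max(1L, pos - max_scan)
  ch <- strsplit(ref_window(ref, chrom, lo, pos + max_scan), "")[[1]]
  off <- pos - lo + 1L
  if (include_site) {
    idx <- (off - 1L):(off + 1L)
  } else {
    # drop the site base; flanking runs of the same base merge across it
    ch <- ch[-off]
    idx <- c(off - 1L, off)
  }
  idx <- idx[idx >= 1L & idx <= length(ch)]
  if (!length(idx)) return(0L)
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  touch <- vapply(seq_along(starts), function(k)
    any(idx >= starts[k] & idx <= ends[k]), logical(1))
  as.integer(max(r$lengths[touch]))
}

#' Transition vs transversion
#'
#' A substitution is a transition iff it is A<->G or C<->T; the other four
#' unordered base pairs are transversions. Symmetric in (ref, alt).
#'
#' @param ref_base,alt_base single bases in `A,C,G,T`; `ref_base != alt_base`.
#' @return logical.
#' @export
is_transition <- function(ref_base, alt_base) {
  if (!all(c(ref_base, alt_base) %in% c("A","C","G","T")))
    stop("invalid base")
  if (any(ref_base == alt_base)) stop("ref and alt must differ")
  purine <- c("A", "G")
  (ref_base %in% purine) == (alt_base %in% purine)
}

#' Transition/transversion ratio of a site set
#'
#' @param ref_bases,alt_bases parallel allele vectors.
#' @return `#transitions / #transversions`; when there are no transversions
#'   the value is `Inf` with attribute `undefined = TRUE`.
#' @export
titv_ratio <- function(ref_bases, alt_bases) {
  if (!length(ref_bases)) stop("empty site set")
  ti <- mapply(is_transition, ref_bases, alt_bases)
  n_ti <- sum(ti); n_tv <- sum(!ti)
  if (n_tv == 0L) return(structure(Inf, undefined = TRUE))
  n_ti / n_tv
}

#' Annotate a panel with locus features
#'
#' @param panel a [site_panel].
#' @param ref a [ref_store].
#' @param flank GC window flank.
#' @param include_site homopolymer convention, see [homopolymer_length()].
#' @return data.table: chrom, pos, ref, alt, gc, homopolymer, transition.
#' @export
annotate_features <- function(panel, ref, flank = 50L, include_site = TRUE) {
  store <- ref   # 'ref' is also a panel column name inside j-expressions
  dt <- as.data.table(panel)[, .(chrom, pos, ref, alt)]
  dt[, gc := vapply(seq_len(.N), function(i)
    gc_content(store, chrom[i], pos[i], flank), numeric(1))]
  dt[, homopolymer := vapply(seq_len(.N), function(i)
    homopolymer_length(store, chrom[i], pos[i], include_site), integer(1))]
  dt[, transition := mapply(is_transition, ref, alt)]
  dt[]
}

#' Ti/Tv ratio per concordance class
#'
#' Pools Venn classifications over all samples; each (site, sample) pair
#' contributes once to the class it occupies in that sample, so a site may
#' appear under several classes across samples.
#'
#' @param tensor a [call_tensor].
#' @param features output of [annotate_features()] aligned with the panel.
#' @return data.table: class, n_ti, n_tv, titv.
#' @export
titv_by_class <- function(tensor, features) {
  cls <- rbindlist(lapply(tensor$samples, function(s) classify_venn(tensor, s)))
  cls[, transition := features$transition[site]]
  out <- cls[class != "NONE",
             .(n_ti = sum(transition), n_tv = sum(!transition)), by = class]
  out[, titv := ifelse(n_tv == 0L, NA_real_, n_ti / n_tv)]
  setorder(out, class)
  out[]
}
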