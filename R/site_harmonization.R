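## site_harmonization: derive the common analyzable SNP panel from the two
## target definitions and the array probe set, with provenance counters.

#' Site panel
#'
#' The frozen universe of biallelic autosomal SNP sites shared by all
#' platforms. All downstream modules reference sites by panel row index.
#'
#' @param sites data.table with columns `chrom`, `pos`, `ref`, `alt`.
#' @param counters named list of provenance counters
#'   (`n_common_target_sites`, `n_cnv_removed`, `n_duplicate_probe_groups`,
#'   `n_out_of_target`, ...).
#' @return object of class `site_panel` (a keyed data.table).
#' @export
site_panel <- function(sites, counters = list()) {
  dt <- as.data.table(sites)[, .(chrom = normalize_chrom(chrom),
                                 pos = as.integer(pos),
                                 ref = toupper(ref), alt = toupper(alt))]
  if (anyDuplicated(dt[, .(chrom, pos)]))
    stop("duplicate (chrom, pos) in site panel")
  if (any(dt$ref == dt$alt)) stop("site with ref == alt")
  if (!all(is_autosome(dt$chrom))) stop("non-autosomal site in panel")
  setorder(dt, chrom, pos)
  counters$n_final <- nrow(dt)
  setattr(dt, "counters", counters)
  setattr(dt, "class", c("site_panel", class(dt)))
  dt[]
}

#' @export
print.site_panel <- function(x, ...) {
  cat(sprintf("<site_panel> %d sites\n", nrow(x)))
  cnt <- attr(x, "counters")
  if (length(cnt))
    cat("  counters:", paste(names(cnt), unlist(cnt), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname site_panel
#' @param x a `site_panel`.
#' @export
panel_counters <- function(x) attr(x, "counters") %||% list()

#' Intersect two target definitions
#'
#' Exact interval intersection with half-open semantics; the common target
#' region within which all platform comparisons are made.
#'
#' @param a,b `interval_set`s.
#' @return an `interval_set`.
#' @export
intersect_targets <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  pieces <- lapply(chroms, function(ch) {
    ia <- a[a$chrom == ch]; ib <- b[b$chrom == ch]
    ir <- IRanges::intersect(
      IRanges::IRanges(start = ia$start + 1L, end = ia$end),
      IRanges::IRanges(start = ib$start + 1L, end = ib$end))
    if (!length(ir)) return(NULL)
    data.table(chrom = ch, start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  })
  dt <- rbindlist(pieces)
  if (is.null(dt) || !nrow(dt)) return(interval_set())
  interval_set(dt$chrom, dt$start, dt$end)
}

#' Array probe table
#'
#' Probes are accepted as a CSV manifest with columns `probe_id`, `chrom`,
#' `pos`, `allele_a`, `allele_b`, `strand`, `probe_type` (`"snp"` or `"cnv"`).
#'
#' @param path CSV manifest path.
#' @return data.table with the manifest columns plus logical `is_cnv`.
#' @export
read_manifest <- function(path) {
  dt <- fread(path)
  need <- c("probe_id", "chrom", "pos", "allele_a", "allele_b", "strand",
            "probe_type")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stopf("manifest '%s' lacks column(s): %s", path,
                          paste(miss, collapse = ", "))
  dt[, chrom := normalize_chrom(chrom)]
  dt[, is_cnv := probe_type == "cnv"]
  ok <- dt$is_cnv | (dt$allele_a %in% c("A","C","G","T") &
                     dt$allele_b %in% c("A","C","G","T"))
  if (!all(ok)) stopf("manifest '%s': invalid design alleles at row %d",
                      path, which(!ok)[1])
  dt[]
}

#' Keep probes inside the common target region
#'
#' A probe at 1-based position `p` is inside half-open interval
#' `[start, end)` iff `start < p <= end`.
#'
#' @param probes probe data.table (needs `chrom`, `pos`).
#' @param common an `interval_set`.
#' @return the filtered probes, with attribute `n_out_of_target`.
#' @export
select_common_sites <- function(probes, common) {
  keep <- in_intervals(common, probes$chrom, probes$pos)
  out <- probes[keep]
  setattr(out, "n_out_of_target", sum(!keep))
  out[]
}

#' Remove copy-number-variation probes
#'
#' @param probes probe data.table with logical `is_cnv`.
#' @return SNP probes only, with attribute `n_cnv_removed`.
#' @export
remove_cnv_probes <- function(probes) {
  n_cnv <- sum(probes$is_cnv)
  out <- probes[!probes$is_cnv]
  if (!nrow(out)) warning("all probes were CNV probes; empty panel")
  setattr(out, "n_cnv_removed", n_cnv)
  out[]
}

#' Integrate calls from duplicate probes at one site
#'
#' All non-missing probe calls must agree; any disagreement yields MISSING
#' (conservative, audited via the caller's counters). All-missing yields
#' MISSING. Permutation-invariant in its inputs.
#'
#' @param states integer vector of genotype states from k probes at one site.
#' @return a single genotype state.
#' @export
integrate_duplicate_probes <- function(states) {
  obs <- unique(states[!is.na(states)])
  if (length(obs) == 1L) return(obs)
  NA_integer_   # no call, or probes disagree
}

#' Resolve an observed array allele pair to a genotype state
#'
#' Matches the observed pair to \{ref, alt\} directly or after complementing
#' both alleles. Probes whose ref/alt are themselves complementary (A/T or
#' C/G) cannot be oriented from the alleles alone: they are resolved only
#' when `strand` is `"+"` (design strand equals reference strand) or `"-"`
#' (complement), and are MISSING otherwise (manifest ambiguity).
#'
#' @param a1,a2 observed alleles (`"A"/"C"/"G"/"T"` or `"0"` for no-call).
#' @param ref,alt panel alleles.
#' @param strand `"+"`, `"-"` or `NA`.
#' @return genotype state (integer, `NA` for MISSING/unresolvable).
#' @export
normalize_array_alleles <- function(a1, a2, ref, alt, strand = NA_character_) {
  if (a1 == "0" || a2 == "0") return(NA_integer_)
  if (!all(c(a1, a2) %in% c("A","C","G","T")))
    stopf("invalid observed allele '%s'", setdiff(c(a1, a2), c("A","C","G","T"))[1])
  pair_state <- function(x1, x2) {
    if (!all(c(x1, x2) %in% c(ref, alt))) return(NULL)
    as.integer(sum(c(x1, x2) == alt))
  }
  ambiguous <- alt == complement_base(ref)
  if (ambiguous) {
    if (is.na(strand)) return(NA_integer_)
    if (strand == "+") return(pair_state(a1, a2) %||% NA_integer_)
    return(pair_state(complement_base(a1), complement_base(a2)) %||% NA_integer_)
  }
  st <- pair_state(a1, a2)
  if (!is.null(st)) return(st)
  st <- pair_state(complement_base(a1), complement_base(a2))
  if (!is.null(st)) return(st)
  NA_integer_   # alleles match neither strand reading: treated as no-call
}

#' Build the harmonized site panel from probes and target definitions
#'
#' Applies the harmonization chain: intersect the two target definitions,
#' keep probes inside the common region, drop CNV probes, collapse duplicate
#' probes at the same position to one site, and attach ref/alt. The alternate
#' allele per site is the design allele differing from the reference base
#' (after strand resolution where needed).
#'
#' @param probes probe data.table from [read_manifest()].
#' @param target_a,target_b the two target `interval_set`s (exome capture and
#'   array coverage).
#' @param ref a [ref_store] supplying the reference base per site.
#' @return a [site_panel] with provenance counters; probes whose design
#'   alleles cannot yield a ref-consistent alt are dropped and counted
#'   (`n_allele_mismatch`).
#' @export
build_site_panel <- function(probes, target_a, target_b, ref) {
  common <- intersect_targets(target_a, target_b)
  inb <- select_common_sites(probes, common)
  n_out <- attr(inb, "n_out_of_target")
  snp <- remove_cnv_probes(inb)
  n_cnv <- attr(snp, "n_cnv_removed")
  n_common_sites <- length(unique(paste(snp$chrom, snp$pos)))

  grp <- snp[, .N, by = .(chrom, pos)]
  n_dup_groups <- sum(grp$N > 1L)

  uniq <- snp[!duplicated(paste(chrom, pos))]
  refb <- vapply(seq_len(nrow(uniq)),
                 function(i) ref_base(ref, uniq$chrom[i], uniq$pos[i]),
                 character(1))
  alt <- character(nrow(uniq)); ok <- logical(nrow(uniq))
  for (i in seq_len(nrow(uniq))) {
    des <- c(uniq$allele_a[i], uniq$allele_b[i])
    cand <- if (refb[i] %in% des) des else complement_base(des)
    if (refb[i] %in% cand && length(unique(cand)) == 2L) {
      alt[i] <- setdiff(cand, refb[i])[1]; ok[i] <- TRUE
    }
  }
  counters <- list(n_probes_in = nrow(probes),
                   n_out_of_target = n_out,
                   n_common_target_sites = n_common_sites,
                   n_cnv_removed = n_cnv,
                   n_duplicate_probe_groups = n_dup_groups,
                   n_duplicates_collapsed = nrow(snp) - nrow(uniq),
                   n_allele_mismatch = sum(!ok))
  site_panel(data.table(chrom = uniq$chrom[ok], pos = uniq$pos[ok],
                        ref = refb[ok], alt = alt[ok]),
             counters = counters)
}

#' Export a panel as BED + TSV with provenance counters
#'
#' @param panel a [site_panel].
#' @param bed_path,tsv_path output paths.
#' @export
export_panel <- function(panel, bed_path, tsv_path) {
  dt <- as.data.table(panel)
  fwrite(dt[, .(chrom, start = pos - 1L, end = pos)], bed_path,
         sep = "\t", col.names = FALSE)
  cnt <- panel_counters(panel)
  hdr <- paste0("# ", paste(names(cnt), unlist(cnt), sep = "=", collapse = " "))
  writeLines(c(hdr, paste(c("chrom","pos","ref","alt"), collapse = "\t"),
               dt[, paste(chrom, pos, ref, alt, sep = "\t")]), tsv_path)
  invisible(tsv_path)
}
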