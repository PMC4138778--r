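## variant_io: readers/writers for the standard formats the pipeline touches
## (VCF, PLINK PED/MAP, BED, FASTA) and the internal call/site model.

# ---------------------------------------------------------------------------
# interval sets ----

#' Interval sets (BED semantics)
#'
#' An `interval_set` is a normalized list of genomic intervals in 0-based
#' half-open coordinates, restricted to autosomes, sorted and merged.
#'
#' @param chrom character chromosome labels.
#' @param start,end integer bounds, 0-based half-open (`end > start`).
#' @return an object of class `interval_set`: a `data.table` with columns
#'   `chrom`, `start`, `end`.
#' @export
interval_set <- function(chrom = character(), start = integer(), end = integer()) {
  dt <- data.table(chrom = normalize_chrom(chrom),
                   start = as.integer(start), end = as.integer(end))
  if (nrow(dt) && any(dt$end <= dt$start))
    stopf("interval with end <= start at row %d", which(dt$end <= dt$start)[1])
  normalize_intervals(dt)
}

## sort + merge overlapping/adjacent-overlapping intervals via IRanges
normalize_intervals <- function(dt) {
  if (nrow(dt)) {
    pieces <- lapply(split(dt, by = "chrom", sorted = TRUE), function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
      data.table(chrom = d$chrom[1],
                 start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    })
    dt <- rbindlist(pieces)
    setorder(dt, chrom, start)
  }
  setattr(dt, "class", c("interval_set", class(dt)))
  dt[]
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d intervals, %d chromosomes, %d bases\n",
              nrow(x), length(unique(x$chrom)), interval_total_length(x)))
  if (nrow(x)) print(as.data.table(x), topn = 3)
  invisible(x)
}

#' Total length of an interval set in bases
#' @param x an `interval_set`.
#' @export
interval_total_length <- function(x) if (nrow(x)) sum(x$end - x$start) else 0L

#' Membership of 1-based points in an interval set
#'
#' A 1-based position `p` lies in half-open interval `[start, end)` iff
#' `start < p <= end`.
#'
#' @param x an `interval_set`.
#' @param chrom,pos parallel vectors of chromosome labels and 1-based positions.
#' @return logical vector.
#' @export
in_intervals <- function(x, chrom, pos) {
  chrom <- normalize_chrom(chrom)
  out <- logical(length(pos))
  if (!nrow(x)) return(out)
  for (ch in unique(chrom)) {
    iv <- x[x$chrom == ch]
    if (!nrow(iv)) next
    idx <- which(chrom == ch)
    ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    out[idx] <- IRanges::overlapsAny(
      IRanges::IRanges(start = pos[idx], width = 1L), ir)
  }
  out
}

#' Read a BED file into an interval_set
#'
#' Accepts BED3+ (extra columns ignored), 0-based half-open. Non-autosomal
#' lines are dropped (their count is reported as attribute
#' `n_dropped_nonautosomal` and via a message).
#'
#' @param path path to a BED file.
#' @param quiet suppress the dropped-line message.
#' @return an `interval_set`.
#' @export
read_bed <- function(path, quiet = FALSE) {
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", fill = TRUE),
    error = function(e) stopf("failed to read BED '%s': %s", path, conditionMessage(e)))
  if (!nrow(dt)) return(interval_set())
  if (ncol(dt) < 3) stopf("BED '%s' has fewer than 3 columns", path)
  setnames(dt, 1:3, c("chrom", "start", "end"))
  bad <- which(dt$end <= dt$start)
  if (length(bad)) stopf("BED '%s': end <= start at line %d", path, bad[1])
  dt[, chrom := normalize_chrom(chrom)]
  drop <- !is_autosome(dt$chrom)
  if (any(drop) && !quiet)
    message(sprintf("read_bed: dropped %d non-autosomal interval(s)", sum(drop)))
  out <- interval_set(dt$chrom[!drop], dt$start[!drop], dt$end[!drop])
  setattr(out, "n_dropped_nonautosomal", sum(drop))
  out
}

#' Write an interval_set as BED3
#' @param x an `interval_set`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  fwrite(as.data.table(x)[, .(chrom, start, end)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# reference store ----

#' Reference sequence store
#'
#' Thin wrapper over named upper-case chromosome strings with bounds-checked
#' 1-based lookups.
#'
#' @param seqs named character vector (or `DNAStringSet`), one element per
#'   chromosome.
#' @return object of class `ref_store`.
#' @export
ref_store <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyNA(names(seqs)))
    stop("reference sequences must be named by chromosome")
  seqs <- toupper(seqs)
  names(seqs) <- normalize_chrom(names(seqs))
  structure(list(seqs = seqs), class = "ref_store")
}

#' @export
print.ref_store <- function(x, ...) {
  cat(sprintf("<ref_store> %d sequence(s), %d bases total\n",
              length(x$seqs), sum(nchar(x$seqs))))
  invisible(x)
}

ref_check <- function(ref, chrom, pos) {
  chrom <- normalize_chrom(chrom)
  if (!chrom %in% names(ref$seqs)) stopf("chromosome '%s' not in reference", chrom)
  n <- nchar(ref$seqs[[chrom]])
  if (any(pos < 1L | pos > n))
    stopf("position %d out of range for chromosome '%s' (length %d)",
          pos[which(pos < 1L | pos > n)[1]], chrom, n)
  chrom
}

#' @rdname ref_store
#' @param ref a `ref_store`.
#' @param chrom chromosome label.
#' @param pos 1-based position(s) on that chromosome.
#' @export
ref_base <- function(ref, chrom, pos) {
  chrom <- ref_check(ref, chrom, pos)
  vapply(pos, function(p) substr(ref$seqs[[chrom]], p, p), character(1))
}

#' @rdname ref_store
#' @param start,end 1-based inclusive window bounds (clipped to the sequence).
#' @export
ref_window <- function(ref, chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  if (!chrom %in% names(ref$seqs)) stopf("chromosome '%s' not in reference", chrom)
  n <- nchar(ref$seqs[[chrom]])
  substr(ref$seqs[[chrom]], max(1L, start), min(n, end))
}

#' @rdname ref_store
#' @export
ref_chrom_length <- function(ref, chrom) {
  chrom <- normalize_chrom(chrom)
  if (!chrom %in% names(ref$seqs)) stopf("chromosome '%s' not in reference", chrom)
  nchar(ref$seqs[[chrom]])
}

#' Read / write reference FASTA
#'
#' Backed by [Biostrings::readDNAStringSet()]; sequence names are taken up to
#' the first whitespace, bases upper-cased.
#'
#' @param path FASTA path.
#' @return `read_fasta`: a [ref_store].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  ref_store(ss)
}

#' @rdname read_fasta
#' @param ref a `ref_store`.
#' @export
write_fasta <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(ref$seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# VCF ----

#' Read genotype calls from a multi-sample VCF
#'
#' Parses VCF 4.x with a per-sample `GT` field (required) and `DP` (optional).
#' Only biallelic autosomal SNPs are retained as-is; multi-allelic SNP records
#' are collapsed to alt-positive vs reference: the retained alt allele is the
#' cohort-wise most frequent alt at the record (ties broken by alphabetical
#' order), genotypes with two identical non-reference alleles become hom-alt
#' and any other genotype carrying a non-reference allele becomes het.
#' Indels and non-autosomal records are dropped with counters.
#'
#' @param path VCF path (plain text).
#' @param platform platform label stamped on every call.
#' @return a list with elements
#'   `calls` (`data.table`: chrom, pos, ref, alt, sample_id, platform, state,
#'   depth), `sites` (`data.table`: chrom, pos, ref, alt), `samples`
#'   (character), and drop counters `n_dropped_nonautosomal`,
#'   `n_dropped_indel`, `n_collapsed_multiallelic`.
#' @export
read_vcf <- function(path, platform = "unknown") {
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) stopf("VCF '%s': no #CHROM header line", path)
  hdr <- hdr[1]
  header <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(header) < 10) stopf("VCF '%s': no sample columns", path)
  samples <- header[-(1:9)]
  body_idx <- which(!startsWith(lines, "#"))
  body_idx <- body_idx[body_idx > hdr & nzchar(lines[body_idx])]

  n_nonauto <- 0L; n_indel <- 0L; n_multi <- 0L
  out <- vector("list", length(body_idx))
  sites <- vector("list", length(body_idx))

  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stopf("VCF '%s' line %d: expected %d fields, found %d",
            path, i, length(header), length(f))
    chrom <- normalize_chrom(f[1])
    if (!is_autosome(chrom)) { n_nonauto <- n_nonauto + 1L; next }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stopf("VCF '%s' line %d: bad POS '%s'", path, i, f[2])
    refa <- toupper(f[4]); alts <- toupper(strsplit(f[5], ",", fixed = TRUE)[[1]])
    if (nchar(refa) != 1L || !refa %in% c("A","C","G","T") ||
        any(nchar(alts) != 1L) || !all(alts %in% c("A","C","G","T"))) {
      n_indel <- n_indel + 1L; next
    }
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt); dp_i <- match("DP", fmt)
    if (is.na(gt_i))
      stopf("VCF '%s' line %d (%s:%d): FORMAT lacks GT", path, i, chrom, pos)
    entries <- strsplit(f[-(1:9)], ":", fixed = TRUE)
    gts <- vapply(entries, function(e) e[gt_i], character(1))
    alleles <- strsplit(gts, "[/|]")
    idx <- lapply(alleles, function(a) suppressWarnings(as.integer(a)))
    bad <- vapply(idx, function(a)
      length(a) != 2L && !all(is.na(a)), logical(1))
    if (any(bad))
      stopf("VCF '%s' line %d: malformed GT '%s'", path, i, gts[which(bad)[1]])

    if (length(alts) > 1L) {
      n_multi <- n_multi + 1L
      cnt <- tabulate(unlist(idx)[!is.na(unlist(idx)) & unlist(idx) > 0L],
                      nbins = length(alts))
      keep <- order(-cnt, alts)[1]   # most frequent alt, tie -> smallest base
      alt <- alts[keep]
    } else alt <- alts[1]

    state <- vapply(idx, function(a) {
      if (anyNA(a)) return(NA_integer_)
      if (all(a == 0L)) return(GT_HOM_REF)
      if (a[1] == a[2]) return(GT_HOM_ALT)
      GT_HET
    }, integer(1))

    depth <- if (!is.na(dp_i)) {
      vapply(entries, function(e) {
        d <- if (length(e) >= dp_i) suppressWarnings(as.integer(e[dp_i])) else NA_integer_
        if (is.na(d)) NA_integer_ else d
      }, integer(1))
    } else rep(NA_integer_, length(samples))

    out[[k]] <- data.table(chrom = chrom, pos = pos, ref = refa, alt = alt,
                           sample_id = samples, platform = platform,
                           state = state, depth = depth)
    sites[[k]] <- data.table(chrom = chrom, pos = pos, ref = refa, alt = alt)
  }
  calls <- rbindlist(out)
  if (!nrow(calls))
    calls <- data.table(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), sample_id = character(),
                        platform = character(), state = integer(),
                        depth = integer())
  site_dt <- unique(rbindlist(sites))
  if (!is.null(site_dt)) setorder(site_dt, chrom, pos)
  list(calls = calls, sites = site_dt, samples = samples,
       n_dropped_nonautosomal = n_nonauto, n_dropped_indel = n_indel,
       n_collapsed_multiallelic = n_multi)
}

#' Write a platform slice of a call tensor as a multi-sample VCF
#'
#' Emits `GT` always and `DP` when a depth matrix is supplied. MISSING states
#' are written as `./.`. `read_vcf(write_vcf(...))` round-trips (site, sample,
#' state, depth).
#'
#' @param panel a [site_panel] (or data.table with chrom/pos/ref/alt).
#' @param states integer matrix, sites x samples (0/1/2/NA).
#' @param samples sample labels (columns of `states`).
#' @param path output path.
#' @param depths optional integer matrix parallel to `states`.
#' @export
write_vcf <- function(panel, states, samples, path, depths = NULL) {
  sites <- as.data.table(panel)
  if (nrow(sites) != nrow(states) || length(samples) != ncol(states))
    stop("states matrix does not match panel/samples")
  gt_str <- matrix("./.", nrow(states), ncol(states))
  gt_str[!is.na(states) & states == GT_HOM_REF] <- "0/0"
  gt_str[!is.na(states) & states == GT_HET]     <- "0/1"
  gt_str[!is.na(states) & states == GT_HOM_ALT] <- "1/1"
  has_dp <- !is.null(depths)
  if (has_dp) {
    dp_str <- ifelse(is.na(depths), ".", as.character(depths))
    cell <- matrix(paste(gt_str, dp_str, sep = ":"), nrow(states))
  } else cell <- gt_str
  fmt <- if (has_dp) "GT:DP" else "GT"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               if (has_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO","FORMAT",
                       samples), collapse = "\t")), con)
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".", ".",
                ".", fmt, sep = "\t")
  body <- paste(body, apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# PLINK PED/MAP ----

#' Read array genotypes from a PLINK classic PED/MAP pair
#'
#' MAP supplies site order (chrom, id, cM, pos); the panel supplies ref/alt.
#' Observed allele pairs are resolved to genotype states relative to the panel
#' alleles via [normalize_array_alleles()] (direct match or complement-strand
#' flip; unresolvable strand-ambiguous probes become MISSING). `0 0` is
#' MISSING.
#'
#' @param ped_path,map_path PLINK text files.
#' @param panel a [site_panel] giving ref/alt per (chrom, pos); MAP sites
#'   absent from the panel are dropped with a counter.
#' @param strand optional named character vector of `"+"`/`"-"` design-strand
#'   annotations keyed by `paste(chrom, pos)`, used to resolve
#'   strand-ambiguous (A/T, C/G) probes.
#' @param platform platform label for the calls.
#' @return list with `calls` (data.table as in [read_vcf()]), `samples`,
#'   `n_dropped_not_in_panel`, `n_manifest_ambiguous`.
#' @export
read_plink <- function(ped_path, map_path, panel, strand = NULL,
                       platform = "array") {
  map <- fread(map_path, header = FALSE, sep = "\t")
  if (ncol(map) == 1) map <- fread(map_path, header = FALSE)
  if (ncol(map) < 4) stopf("MAP '%s': expected 4 columns", map_path)
  setnames(map, 1:4, c("chrom", "id", "cm", "pos"))
  map[, chrom := normalize_chrom(chrom)]
  ped <- fread(ped_path, header = FALSE, colClasses = "character")
  need <- 6L + 2L * nrow(map)
  if (ncol(ped) != need)
    stopf("PED '%s': %d columns, expected %d (6 + 2 x %d MAP rows)",
          ped_path, ncol(ped), need, nrow(map))
  samples <- ped[[2]]

  sites <- as.data.table(panel)
  mkey <- paste(map$chrom, map$pos)
  pkey <- paste(sites$chrom, sites$pos)
  hit <- match(mkey, pkey)
  n_drop <- sum(is.na(hit))
  n_amb <- 0L
  res <- vector("list", nrow(map))
  for (j in seq_len(nrow(map))) {
    if (is.na(hit[j])) next
    s <- sites[hit[j]]
    a1 <- toupper(ped[[6L + 2L * j - 1L]]); a2 <- toupper(ped[[6L + 2L * j]])
    str_j <- if (!is.null(strand)) unname(strand[mkey[j]]) else NA_character_
    if (is.null(str_j) || length(str_j) != 1L) str_j <- NA_character_
    st <- mapply(normalize_array_alleles, a1, a2,
                 MoreArgs = list(ref = s$ref, alt = s$alt, strand = str_j),
                 USE.NAMES = FALSE)
    n_amb <- n_amb + sum(is.na(st) & !(a1 == "0" | a2 == "0"))
    res[[j]] <- data.table(chrom = s$chrom, pos = s$pos, ref = s$ref,
                           alt = s$alt, sample_id = samples,
                           platform = platform, state = as.integer(st),
                           depth = NA_integer_)
  }
  calls <- rbindlist(res)
  list(calls = calls, samples = samples,
       n_dropped_not_in_panel = n_drop, n_manifest_ambiguous = n_amb)
}

#' Write a PLINK PED/MAP pair for an array platform slice
#'
#' @inheritParams write_vcf
#' @param ped_path,map_path output paths.
#' @param flip logical vector per site: emit the allele pair on the opposite
#'   strand (simulates manifest strand flips).
#' @export
write_plink <- function(panel, states, samples, ped_path, map_path,
                        flip = NULL) {
  sites <- as.data.table(panel)
  n <- nrow(sites)
  if (is.null(flip)) flip <- rep(FALSE, n)
  ref <- sites$ref; alt <- sites$alt
  ref[flip] <- complement_base(ref[flip]); alt[flip] <- complement_base(alt[flip])
  map <- data.table(chrom = sites$chrom,
                    id = paste0("snp", seq_len(n), "_", sites$chrom, "_", sites$pos),
                    cm = 0L, pos = sites$pos)
  fwrite(map, map_path, sep = "\t", col.names = FALSE)
  a1 <- matrix("0", n, length(samples)); a2 <- a1
  for (s in seq_along(samples)) {
    st <- states[, s]
    a1[, s] <- ifelse(is.na(st), "0", ifelse(st == GT_HOM_ALT, alt, ref))
    a2[, s] <- ifelse(is.na(st), "0", ifelse(st == GT_HOM_REF, ref, alt))
  }
  rows <- vapply(seq_along(samples), function(s)
    paste(c(paste0("FAM", s), samples[s], "0", "0", "0", "-9",
            as.vector(rbind(a1[, s], a2[, s]))), collapse = "\t"),
    character(1))
  writeLines(rows, ped_path)
  invisible(ped_path)
}
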