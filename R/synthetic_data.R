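## synthetic_data: deterministic generator for complete three-platform call
## sets with known truth and known error structure, so every pipeline stage
## is testable without external data.

## run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic world; the seed is mandatory and
#' all randomness derives from it. Defaults emulate the study design the
#' pipeline targets: 12 diploid samples, alt allele frequencies uniform on
#' \[0.05, 0.95\] (so 12-sample allele counts span 0..24), WGS depth around
#' 32x and exome depth around 109x, a GC- and homopolymer-sensitive miss
#' process on the exome platform, a depth-dominated one on the WGS platform,
#' and array extras (duplicate probe groups at ~3.2% of sites, 6 CNV probes,
#' manifest-flipped probes at ~0.25% of sites).
#'
#' @param n_sites number of SNP sites.
#' @param n_samples number of diploid samples (>= 2).
#' @param seed integer seed (mandatory).
#' @param spacing bases between consecutive sites (>= 2 x flank + 1).
#' @param gc_gradient length-2 vector: GC probability at the start/end of
#'   each chromosome (flat when equal).
#' @param homopolymer_rate fraction of sites with a planted adjacent
#'   homopolymer run (length 4-9).
#' @param freq_range alt allele frequency range (uniform draw).
#' @param wgs,exome,array per-platform error models, see [error_model()].
#' @param n_duplicate_probe_groups,dup_group_size,n_cnv_probes,
#'   n_manifest_flip_probes array manifest extras.
#' @param exome_target_fraction fraction of sites covered by the exome
#'   target BED (from the start of each chromosome).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_sites = 5000L, n_samples = 12L, seed,
                       spacing = 250L, gc_gradient = c(0.30, 0.65),
                       homopolymer_rate = 0.15,
                       freq_range = c(0.05, 0.95),
                       wgs = error_model("wgs"),
                       exome = error_model("exome"),
                       array = error_model("array"),
                       n_duplicate_probe_groups = round(0.032 * n_sites),
                       dup_group_size = 2L,
                       n_cnv_probes = 6L,
                       n_manifest_flip_probes = round(0.0025 * n_sites),
                       exome_target_fraction = 1.0) {
  if (missing(seed)) stop("seed is mandatory: no implicit randomness")
  if (n_samples < 2L) stop("n_samples must be >= 2")
  if (n_sites < 1L) stop("n_sites must be >= 1")
  stopifnot(all(freq_range >= 0 & freq_range <= 1),
            homopolymer_rate >= 0, homopolymer_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Per-platform error model
#'
#' The miss probability of a call at a (site, sample) is
#' `plogis(b0 + b_depth * (depth_mean - depth) + b_gc * gc + b_homo * hp)`:
#' the depth covariate is the depth *deficit*, so a positive `b_depth` makes
#' low-coverage calls more likely to be missed. A missed alt-positive truth
#' is emitted as hom-ref (NGS VCFs omit non-variant sites, so a missed call
#' surfaces as reference downstream). Miscalls replace the call with a
#' uniformly chosen different state. The array platform has no depth: it
#' applies a flat no-call rate (MISSING) and a miscall rate.
#'
#' @param platform `"wgs"`, `"exome"` or `"array"`.
#' @param ... overrides of the per-platform defaults.
#' @return object of class `error_model`.
#' @export
error_model <- function(platform = c("wgs", "exome", "array"), ...) {
  platform <- match.arg(platform)
  defaults <- switch(platform,
    wgs   = list(type = "ngs", depth_mean = 32.4, depth_size = 10,
                 b0 = -5.5, b_depth = 0.08, b_gc = 0.5, b_homo = 0.01,
                 miscall = 0.001),
    exome = list(type = "ngs", depth_mean = 109, depth_size = 5,
                 b0 = -4.5, b_depth = 0.02, b_gc = 2.0, b_homo = 0.12,
                 miscall = 0.001),
    array = list(type = "array", no_call = 0.002, miscall = 0.001))
  ov <- list(...)
  bad <- setdiff(names(ov), names(defaults))
  if (length(bad)) stopf("unknown error_model field(s): %s", paste(bad, collapse = ", "))
  defaults[names(ov)] <- ov
  structure(c(list(platform = platform), defaults), class = "error_model")
}

#' Zero-error variant of a platform error model (all rates off)
#' @param model an [error_model()].
#' @export
zero_error <- function(model) {
  if (model$type == "ngs") {
    model$b0 <- -1e6; model$b_depth <- 0; model$b_gc <- 0; model$b_homo <- 0
    model$miscall <- 0
  } else {
    model$no_call <- 0; model$miscall <- 0
  }
  model
}

#' Generate a synthetic reference and site panel
#'
#' One chromosome per 10,000 sites; sites evenly spaced so every GC window
#' fits between neighbours. Base composition follows a per-chromosome GC
#' gradient; a configurable fraction of sites gets a planted homopolymer run
#' (length 4-9) starting immediately after the site.
#'
#' @param n_sites,spacing,gc_gradient,homopolymer_rate,seed see
#'   [sim_config()].
#' @param flank GC window flank (spacing must exceed `2 * flank`).
#' @return list: `ref` (a [ref_store]), `panel` (a [site_panel]).
#' @export
generate_reference <- function(n_sites, spacing = 250L,
                               gc_gradient = c(0.30, 0.65),
                               homopolymer_rate = 0.15, seed, flank = 50L) {
  if (missing(seed)) stop("seed is mandatory")
  if (spacing < 2L * flank + 1L)
    stopf("infeasible spacing %d: need >= %d so GC windows fit", spacing,
          2L * flank + 1L)
  with_seed(seed, {
    n_chrom <- ceiling(n_sites / 10000L)
    per <- diff(floor(seq(0, n_sites, length.out = n_chrom + 1L)))
    sites <- vector("list", n_chrom)
    seqs <- character(n_chrom)
    for (ci in seq_len(n_chrom)) {
      k <- per[ci]
      if (k == 0L) next
      len <- (k + 1L) * spacing
      gc_prob <- gc_gradient[1] +
        (gc_gradient[2] - gc_gradient[1]) * (seq_len(len) - 1) / max(1L, len - 1L)
      is_gc <- runif(len) < gc_prob
      base <- ifelse(is_gc, sample(c("G", "C"), len, replace = TRUE),
                     sample(c("A", "T"), len, replace = TRUE))
      pos <- spacing * seq_len(k)
      planted <- runif(k) < homopolymer_rate
      for (i in which(planted)) {
        L <- sample(4:9, 1)
        b <- sample(c("A", "C", "G", "T"), 1)
        base[(pos[i] + 1L):(pos[i] + L)] <- b
      }
      refb <- base[pos]
      alt <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      seqs[ci] <- paste(base, collapse = "")
      sites[[ci]] <- data.table(chrom = as.character(ci), pos = pos,
                                ref = refb, alt = alt)
    }
    names(seqs) <- as.character(seq_len(n_chrom))
    list(ref = ref_store(seqs),
         panel = site_panel(rbindlist(sites),
                            counters = list(n_generated = n_sites)))
  })
}

#' Simulate Hardy-Weinberg truth genotypes
#'
#' Per site, an alt allele frequency is drawn uniformly from `freq_range`;
#' per sample, the genotype is Binomial(2, p) alt alleles (HWE, i.i.d.).
#'
#' @param panel a [site_panel].
#' @param n_samples number of samples.
#' @param freq_range alt-frequency range (degenerate range = fixed p).
#' @param seed integer seed.
#' @return list: `panel`, `freq` (per-site p), `geno` (sites x samples
#'   integer matrix), `samples`.
#' @export
simulate_truth <- function(panel, n_samples = 12L, freq_range = c(0.05, 0.95),
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  with_seed(seed, {
    n <- nrow(panel)
    p <- runif(n, freq_range[1], freq_range[2])
    geno <- matrix(rbinom(n * n_samples, 2L, rep(p, n_samples)),
                   nrow = n, ncol = n_samples)
    samples <- sprintf("S%02d", seq_len(n_samples))
    colnames(geno) <- samples
    list(panel = panel, freq = p, geno = geno, samples = samples)
  })
}

#' Realize one platform's calls from the truth
#'
#' Applies the platform's [error_model()]: depth draw (negative binomial),
#' logit-linear miss process on depth deficit / GC / homopolymer length,
#' then a flat miscall process. See [error_model()] for the emission rules.
#'
#' @param truth output of [simulate_truth()].
#' @param features [annotate_features()] output aligned with the panel.
#' @param model an [error_model()].
#' @param seed integer seed.
#' @return list: `states` (sites x samples), `depths` (or NULL for array),
#'   `events` (data.table of injected error events: site, sample, type).
#' @export
simulate_platform <- function(truth, features, model, seed) {
  if (missing(seed)) stop("seed is mandatory")
  with_seed(seed, {
    n <- nrow(truth$geno); ns <- ncol(truth$geno)
    states <- truth$geno
    events <- list()
    if (model$type == "ngs") {
      depths <- matrix(rnbinom(n * ns, size = model$depth_size,
                               mu = model$depth_mean), n, ns)
      miss_p <- plogis(model$b0 +
                         model$b_depth * (model$depth_mean - depths) +
                         model$b_gc * features$gc +
                         model$b_homo * features$homopolymer)
      missed <- matrix(runif(n * ns) < miss_p, n, ns)
      # a missed call surfaces as hom-ref (the variant record is simply absent)
      changed <- missed & states != GT_HOM_REF
      states[missed] <- GT_HOM_REF
      idx <- which(changed, arr.ind = TRUE)
      if (nrow(idx))
        events$miss <- data.table(site = idx[, 1], sample = truth$samples[idx[, 2]],
                                  type = "miss")
    } else {
      depths <- NULL
      nc <- matrix(runif(n * ns) < model$no_call, n, ns)
      states[nc] <- NA_integer_
      idx <- which(nc, arr.ind = TRUE)
      if (nrow(idx))
        events$no_call <- data.table(site = idx[, 1],
                                     sample = truth$samples[idx[, 2]],
                                     type = "no_call")
    }
    mc <- matrix(runif(n * ns) < model$miscall, n, ns) & !is.na(states)
    if (any(mc)) {
      shift <- matrix(sample(1:2, n * ns, replace = TRUE), n, ns)
      states[mc] <- (states[mc] + shift[mc]) %% 3L
      idx <- which(mc, arr.ind = TRUE)
      events$miscall <- data.table(site = idx[, 1],
                                   sample = truth$samples[idx[, 2]],
                                   type = "miscall")
    }
    colnames(states) <- truth$samples
    if (!is.null(depths)) colnames(depths) <- truth$samples
    list(states = states, depths = depths,
         events = if (length(events)) rbindlist(events) else
           data.table(site = integer(), sample = character(), type = character()))
  })
}

#' Run the whole simulation
#'
#' Generates the reference and panel, annotates features, draws truth
#' genotypes and realizes the three platforms (seeds for the sub-stages are
#' derived deterministically from `config$seed`). Array extras (duplicate
#' probe groups, CNV probes, manifest flips) are assigned here and take
#' effect in the emitted fixtures; duplicate-probe replicates are integrated
#' with [integrate_duplicate_probes()] before entering the in-memory tensor.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `ref`, `panel`, `features`, `truth`,
#'   `tensor` (a [call_tensor]), `platforms` (raw per-platform results),
#'   `events`, `probe_assignments`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gen <- generate_reference(config$n_sites, config$spacing, config$gc_gradient,
                            config$homopolymer_rate, seed = config$seed)
  features <- annotate_features(gen$panel, gen$ref)
  truth <- simulate_truth(gen$panel, config$n_samples, config$freq_range,
                          seed = config$seed + 1L)
  wgs <- simulate_platform(truth, features, config$wgs, seed = config$seed + 2L)
  exo <- simulate_platform(truth, features, config$exome, seed = config$seed + 3L)
  arr <- simulate_platform(truth, features, config$array, seed = config$seed + 4L)

  n <- nrow(gen$panel)
  assignments <- with_seed(config$seed + 5L, {
    dup_sites <- if (config$n_duplicate_probe_groups > 0)
      sort(sample.int(n, min(config$n_duplicate_probe_groups, n))) else integer()
    ambig <- which(gen$panel$alt == complement_base(gen$panel$ref))
    flip_sites <- if (config$n_manifest_flip_probes > 0 && length(ambig))
      sort(sample(ambig, min(config$n_manifest_flip_probes, length(ambig))))
    else integer()
    list(dup_sites = dup_sites, flip_sites = flip_sites)
  })

  # duplicate-probe replicates: independent error realizations, integrated
  if (length(assignments$dup_sites)) {
    sub_truth <- list(panel = gen$panel[assignments$dup_sites],
                      geno = truth$geno[assignments$dup_sites, , drop = FALSE],
                      samples = truth$samples)
    for (rep_i in seq_len(config$dup_group_size - 1L)) {
      repl <- simulate_platform(sub_truth, features[assignments$dup_sites],
                                config$array, seed = config$seed + 10L + rep_i)
      for (j in seq_along(assignments$dup_sites)) {
        s <- assignments$dup_sites[j]
        for (smp in seq_along(truth$samples)) {
          arr$states[s, smp] <- integrate_duplicate_probes(
            c(arr$states[s, smp], repl$states[j, smp]))
        }
      }
    }
  }

  tensor <- call_tensor(gen$panel,
                        states = list(array = arr$states, wgs = wgs$states,
                                      exome = exo$states),
                        depths = list(wgs = wgs$depths, exome = exo$depths))
  events <- rbindlist(list(
    wgs = wgs$events, exome = exo$events, array = arr$events),
    idcol = "platform")
  list(config = config, ref = gen$ref, panel = gen$panel, features = features,
       truth = truth, tensor = tensor,
       platforms = list(wgs = wgs, exome = exo, array = arr),
       events = events, probe_assignments = assignments)
}

#' Emit standard-format fixtures from a simulation
#'
#' Writes the reference FASTA, exome and array target BEDs, three
#' multi-sample VCFs (NGS VCFs contain only records where some sample is
#' alt-positive; the array VCF contains every panel site), a PED/MAP pair
#' for the array (manifest-flip probes are emitted on the opposite strand),
#' a CSV probe manifest (including CNV probes and duplicate probe rows),
#' a truth TSV and the injected-event log. Byte-identical for identical
#' configs.
#'
#' @param sim output of [simulate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
emit_fixtures <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stopf("directory '%s' not writable", out_dir)
  pth <- function(f) file.path(out_dir, f)
  panel <- sim$panel; tensor <- sim$tensor
  files <- c(ref = pth("reference.fa"), exome_bed = pth("exome_targets.bed"),
             array_bed = pth("array_targets.bed"),
             wgs_vcf = pth("wgs.vcf"), exome_vcf = pth("exome.vcf"),
             array_vcf = pth("array.vcf"),
             ped = pth("array.ped"), map = pth("array.map"),
             manifest = pth("manifest.csv"),
             truth = pth("truth.tsv"), events = pth("events.tsv"))
  write_fasta(sim$ref, files["ref"])

  # array BED covers every probe position; exome BED covers the configured
  # leading fraction of each chromosome's sites
  dt <- as.data.table(panel)
  write_bed(interval_set(dt$chrom, dt$pos - 1L, dt$pos), files["array_bed"])
  exo_cover <- dt[, .SD[seq_len(ceiling(.N * sim$config$exome_target_fraction))],
                  by = chrom]
  write_bed(interval_set(exo_cover$chrom, exo_cover$pos - 51L,
                         exo_cover$pos + 50L), files["exome_bed"])

  st <- function(p) platform_slice(tensor$state, p)
  dp <- function(p) platform_slice(tensor$depth, p)
  # NGS VCFs: only variant records (some sample alt-positive)
  for (p in c("wgs", "exome")) {
    keep <- rowSums(alt_positive(st(p))) > 0L
    write_vcf(panel[keep], st(p)[keep, , drop = FALSE], tensor$samples,
              files[[paste0(p, "_vcf")]],
              depths = dp(p)[keep, , drop = FALSE])
  }
  write_vcf(panel, st("array"), tensor$samples, files["array_vcf"])

  flip <- seq_len(nrow(panel)) %in% sim$probe_assignments$flip_sites
  write_plink(panel, st("array"), tensor$samples, files["ped"], files["map"],
              flip = flip)

  # manifest: one row per probe; duplicate sites get a second row; CNV probes
  # are extra rows at otherwise-unused positions; flipped probes advertise
  # the design alleles on the opposite strand while claiming "+"
  man <- dt[, .(probe_id = sprintf("probe_%06d", .I), chrom, pos,
                allele_a = ref, allele_b = alt,
                strand = "+", probe_type = "snp")]
  man$allele_a[flip] <- complement_base(man$allele_a[flip])
  man$allele_b[flip] <- complement_base(man$allele_b[flip])
  dup <- man[sim$probe_assignments$dup_sites]
  if (nrow(dup)) dup[, probe_id := sub("probe_", "probedup_", probe_id)]
  cnv <- if (sim$config$n_cnv_probes > 0)
    data.table(probe_id = sprintf("cnv_%03d", seq_len(sim$config$n_cnv_probes)),
               chrom = dt$chrom[1],
               pos = dt$pos[seq_len(min(sim$config$n_cnv_probes, nrow(dt)))] + 1L,
               allele_a = "N", allele_b = "N", strand = "+",
               probe_type = "cnv")
  else NULL
  fwrite(rbindlist(list(man, dup, cnv), use.names = TRUE), files["manifest"])

  truth_dt <- data.table(chrom = dt$chrom, pos = dt$pos, ref = dt$ref,
                         alt = dt$alt, freq = sim$truth$freq)
  truth_dt <- cbind(truth_dt, as.data.table(sim$truth$geno))
  fwrite(truth_dt, files["truth"], sep = "\t")
  fwrite(sim$events, files["events"], sep = "\t")
  files
}
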