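# shared fixture builders: everything generated in code, nothing on disk

# a site_panel of n generic autosomal sites (A>G by default)
toy_panel <- function(n, ref = "A", alt = "G", chrom = "1") {
  site_panel(data.table::data.table(
    chrom = chrom, pos = 100L * seq_len(n), ref = ref, alt = alt))
}

# tensor from explicit per-platform state matrices (sites x samples)
toy_tensor <- function(array, wgs, exome, depths = NULL) {
  n <- nrow(array)
  samples <- sprintf("S%02d", seq_len(ncol(array)))
  colnames(array) <- colnames(wgs) <- colnames(exome) <- samples
  call_tensor(toy_panel(n),
              states = list(array = array, wgs = wgs, exome = exome),
              depths = depths)
}

# random tensor with missing values, fixed seed
random_tensor <- function(n_sites, n_samples, seed, p_missing = 0.05) {
  set.seed(seed)
  rnd <- function() {
    m <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
                n_sites, n_samples)
    m[matrix(runif(n_sites * n_samples) < p_missing,
             n_sites, n_samples)] <- NA_integer_
    m
  }
  toy_tensor(rnd(), rnd(), rnd())
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

vcf_header <- function(samples, fmt_dp = TRUE) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (fmt_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO","FORMAT",
            samples), collapse = "\t"))
}

vcf_line <- function(chrom, pos, ref, alt, fmt, ...) {
  paste(c(chrom, pos, ".", ref, alt, ".", ".", ".", fmt, ...), collapse = "\t")
}

# default zero-error simulation config for pipeline tests
zero_error_config <- function(n_sites = 200L, n_samples = 3L, seed = 11L, ...) {
  sim_config(n_sites = n_sites, n_samples = n_samples, seed = seed,
             wgs = zero_error(error_model("wgs")),
             exome = zero_error(error_model("exome")),
             array = zero_error(error_model("array")),
             n_manifest_flip_probes = 0L, ...)
}
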