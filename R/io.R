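#' Write simulated genotypes as VCF
#'
#' Writes one VCF (4.2, uncompressed text) per gene with phased GT fields,
#' derived-allele coding (REF = A ancestral, ALT = T derived) and an INFO
#' field `MAFA` carrying the deme-A panel minor allele frequency (plus
#' `AFA`, the deme-A derived-allele frequency used to recover the
#' minor-allele orientation on reading).
#'
#' @param g a `genotype_matrix` created with `keep_haplotypes = TRUE`.
#' @param path output file path.
#' @param chrom chromosome/gene label for the CHROM column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, chrom = "gene1") {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(g$haplotypes))
    stopf("phased export requires genotypes built with keep_haplotypes = TRUE")
  # restore derived-allele coding for the VCF body
  H1 <- g$haplotypes$H1; H2 <- g$haplotypes$H2
  flip <- g$flipped
  if (any(flip)) { H1[, flip] <- 1L - H1[, flip]; H2[, flip] <- 1L - H2[, flip] }
  afa <- ifelse(flip, 1 - g$maf_A, g$maf_A)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rvstrat",
               "##INFO=<ID=MAFA,Number=1,Type=Float,Description=\"Minor allele frequency in the full deme-A panel\">",
               "##INFO=<ID=AFA,Number=1,Type=Float,Description=\"Derived (ALT) allele frequency in the full deme-A panel\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  ids <- sprintf("ind%d", seq_len(nrow(H1)))
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  gt <- matrix(paste(t(H1), t(H2), sep = "|"), nrow = ncol(H1))
  lines <- paste(chrom, g$positions, sprintf("%s_%d", chrom, g$positions),
                 "A", "T", ".", "PASS",
                 sprintf("MAFA=%.8g;AFA=%.8g", g$maf_A, afa), "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a genotype matrix
#'
#' Accepts bi-allelic SNVs with GT fields; multi-allelic records are
#' rejected with an explicit error.  Genotypes are recoded to minor-allele
#' counts using the `AFA` INFO field written by [write_vcf()] when present
#' (minor allele relative to the deme-A panel), otherwise the sample allele
#' frequency.
#'
#' @param path VCF file path.
#' @return A `genotype_matrix` (without `origin`; `maf_A` from `MAFA` when
#'   present, else the sample MAF).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) stopf("VCF contains no records")
  alt <- v@fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stopf("multi-allelic record(s) at line(s): %s",
          paste(which(multi), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || any(is.na(gt))) stopf("GT field missing or incomplete")
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  if (any(is.na(a1)) || any(is.na(a2)))
    stopf("malformed GT field(s); diploid GT like 0|1 or 0/1 expected")
  X <- t(matrix(a1 + a2, nrow(gt), ncol(gt)))  # individuals x sites
  positions <- as.integer(v@fix[, "POS"])
  info <- v@fix[, "INFO"]
  afa <- suppressWarnings(as.numeric(sub(".*AFA=([0-9.eE+-]+).*", "\\1", info)))
  has_afa <- grepl("AFA=", info) & !is.na(afa)
  f <- ifelse(has_afa, afa, colMeans(X) / 2)
  flip <- f > 0.5
  if (any(flip)) X[, flip] <- 2L - X[, flip]
  maf <- suppressWarnings(as.numeric(sub(".*MAFA=([0-9.eE+-]+).*", "\\1", info)))
  maf_A <- ifelse(grepl("MAFA=", info) & !is.na(maf), maf,
                  ifelse(flip, 1 - f, f))
  structure(list(X = X, positions = positions, maf_A = maf_A, flipped = flip,
                 origin = factor(rep(NA_character_, nrow(X)), levels = c("A", "B")),
                 region_length_bp = max(positions)),
            class = "genotype_matrix")
}

#' Write / read a phenotype and covariate table
#'
#' Tab-separated with header `id`, `phenotype`, `origin`, then one column
#' per principal component (`PC1`, ...).
#'
#' @param phen a `phenotype_panel`.
#' @param path file path.
#' @param pcs optional matrix of per-individual covariates.
#' @return `path` invisibly; `read_phenotypes` returns a `data.frame`.
#' @export
write_phenotypes <- function(phen, path, pcs = NULL) {
  df <- data.frame(id = sprintf("ind%d", seq_along(phen$Y)),
                   phenotype = phen$Y, origin = as.character(phen$origin))
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    colnames(pcs) <- sprintf("PC%d", seq_len(ncol(pcs)))
    df <- cbind(df, pcs)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write association results as CSV
#'
#' Deterministic column order, full float precision; round-trips exactly at
#' the text representation.
#'
#' @param results a `data.frame` of test results (e.g. from
#'   [run_scenario()]) or a single `rv_test_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "rv_test_result"))
    results <- data.frame(method = results$method, correction = results$correction,
                          statistic = results$statistic, p = results$p,
                          permutations = results$permutations,
                          n_variants = results$n_variants)
  if (!is.data.frame(results) || nrow(results) == 0)
    stopf("results must be a non-empty data.frame")
  first <- intersect(c("replicate", "method", "correction", "statistic", "p",
                       "permutations", "n_variants", "seed"), names(results))
  results <- results[, c(first, setdiff(names(results), first)), drop = FALSE]
  old <- options(digits = 17); on.exit(options(old))
  write.csv(results, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Write / read a run configuration
#'
#' YAML serialization of a demography block, scenario grid, method and
#' correction lists, and seeds.  Reading validates the key set: unknown
#' top-level keys are rejected, and the round trip write -> read is the
#' identity on the stored fields.
#'
#' @param config a named list with any of the keys `demography`,
#'   `scenarios`, `methods`, `corrections`, `seed`, `output_dir`.
#' @param path file path.
#' @return `read_run_config` returns the validated list.
#' @export
write_run_config <- function(config, path) {
  .validate_config_keys(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  .validate_config_keys(config)
  config
}

.config_keys <- c("demography", "scenarios", "methods", "corrections",
                  "seed", "output_dir")

.validate_config_keys <- function(config) {
  if (!is.list(config) || is.null(names(config)))
    stopf("config must be a named list")
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  invisible(TRUE)
}
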