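#' Read a per-SNP allele-frequency table
#'
#' Tab-separated, two columns `snp_id` and `freq` (header required).
#'
#' @param path File path.
#' @return Named numeric vector of frequencies.
#' @export
read_frequency_table <- function(path) {
  if (!file.exists(path)) {
    stop("frequency table not found: ", path, call. = FALSE)
  }
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("snp_id", "freq") %in% names(df))) {
    stop("frequency table needs columns snp_id and freq: ", path, call. = FALSE)
  }
  stats::setNames(df$freq, df$snp_id)
}

#' Write a per-SNP allele-frequency table
#'
#' @param freq Numeric vector (optionally named by SNP id).
#' @param path File path.
#' @export
write_frequency_table <- function(freq, path) {
  ids <- names(freq)
  if (is.null(ids)) ids <- paste0("snp", seq_along(freq))
  write.table(data.frame(snp_id = ids, freq = as.numeric(freq)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Derive an allele-frequency table from a VCF
#'
#' Computes per-site alternate-allele frequencies from the GT field of a
#' (possibly uncompressed) VCF; a convenience converter for feeding observed
#' source panels into [build_reservoir()].
#'
#' @param path VCF file path.
#' @return Named numeric vector of alternate-allele frequencies.
#' @export
vcf_to_frequencies <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("vcfR is required for VCF input", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- apply(gt, 1, function(row) {
    alleles <- unlist(strsplit(row[!is.na(row)], "[/|]"))
    alleles <- alleles[alleles %in% c("0", "1")]
    c(sum(alleles == "1"), length(alleles))
  })
  stats::setNames(counts[1, ] / counts[2, ], rownames(gt))
}

#' Write / read a diploid genotype matrix as TSV
#'
#' Rows are individuals (stable ids in the first column), columns SNP ids,
#' cells 0/1/2.
#'
#' @param genotypes Integer matrix, individuals x SNPs.
#' @param path File path.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(id = rownames(genotypes), genotypes, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_genotypes
#' @return `read_genotypes`: the integer matrix with ids as rownames.
#' @export
read_genotypes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$id
  m
}

#' Write / read a reference table as TSV
#'
#' One row per simulation: `scenario`, the full parameter column set
#' ([param_columns()], NA where a scenario lacks a parameter) and the 42
#' statistics ([summary_stat_names()]).
#'
#' @param table Reference-table data frame.
#' @param path File path.
#' @export
write_reference_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_reference_table
#' @return `read_reference_table`: the data frame.
#' @export
read_reference_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(c(param_columns(), summary_stat_names()), names(df))
  if (length(missing) > 0) {
    stop("reference table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read ancestry segments, ROH intervals and a map from BED-like TSV
#'
#' All coordinates in cM, 0-based half-open. Segments: columns `id`,
#' `haplotype`, `chrom`, `start`, `end`, `ancestry`. ROH: `id`, `chrom`,
#' `start`, `end`. Map: `chrom`, `length`.
#'
#' @param segments_path,roh_path,map_path File paths.
#' @return An `ancestry_roh_track`.
#' @export
read_ancestry_tracks <- function(segments_path, roh_path, map_path) {
  segs <- read.table(segments_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  roh <- read.table(roh_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  map <- read.table(map_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  ancestry_roh_track(segs, roh, map)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file path.
#' @return Named list of settings, with an `md5` attribute of the file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  attr(cfg, "md5") <- unname(tools::md5sum(path))
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  unname(tools::md5sum(tmp))
}
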