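# File formats: dosage TSV, phenotype TSV, VCF, YAML config, JSON logs.

#' Write a dosage matrix as TSV
#'
#' Tab-separated, UTF-8, header row: variant metadata columns (id,
#' chromosome, position, effect_allele, other_allele) followed by one
#' column per individual. Lossless round trip with
#' \code{\link{read_genotypes}}.
#'
#' @param dosages Individuals x variants matrix.
#' @param variant_info Variant metadata aligned to columns of
#'   \code{dosages}.
#' @param path Output path.
#' @export
write_dosage_tsv <- function(dosages, variant_info, path) {
  stopifnot(ncol(dosages) == nrow(variant_info))
  out <- cbind(variant_info[, c("id", "chromosome", "position",
                                "effect_allele", "other_allele")],
               as.data.frame(t(dosages)))
  names(out)[-(1:5)] <- sprintf("ind%d", seq_len(nrow(dosages)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write a cohort's genotypes as a minimal VCF with dosage field
#'
#' VCFv4.2, one sample column per individual, FORMAT "DS" carrying the
#' effect-allele dosage.
#'
#' @param dosages Individuals x variants matrix.
#' @param variant_info Variant metadata.
#' @param path Output path (plain text).
#' @export
write_vcf <- function(dosages, variant_info, path) {
  stopifnot(ncol(dosages) == nrow(variant_info))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       sprintf("ind%d", seq_len(nrow(dosages)))),
                     collapse = "\t")), con)
  body <- vapply(seq_len(nrow(variant_info)), function(j) {
    paste(c(variant_info$chromosome[j], variant_info$position[j],
            variant_info$id[j], variant_info$other_allele[j],
            variant_info$effect_allele[j], ".", ".", ".", "DS",
            format(dosages[, j], trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(body, con)
}

#' Read genotype dosages from VCF or dosage TSV
#'
#' TSV: the format written by \code{\link{write_dosage_tsv}}. VCF: parsed
#' with the vcfR package; the DS (dosage) field is used when present,
#' otherwise GT allele counts. Multi-allelic records are rejected with a
#' reason; positions are 1-based.
#'
#' @param path Input file.
#' @param format "dosage-tsv" or "vcf".
#' @return List with \code{dosages} (individuals x variants, values in
#'   [0, 2]) and \code{variant_info}.
#' @export
read_genotypes <- function(path, format = c("dosage-tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "dosage-tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    meta_cols <- c("id", "chromosome", "position", "effect_allele",
                   "other_allele")
    stopifnot(all(meta_cols %in% names(tab)))
    vi <- tab[, meta_cols]
    dos <- t(as.matrix(tab[, setdiff(names(tab), meta_cols),
                           drop = FALSE]))
    colnames(dos) <- vi$id
    rownames(dos) <- NULL
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"])
    if (any(multi))
      message(sum(multi), " multi-allelic record(s) rejected")
    ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                   error = function(e) NULL)
    if (!is.null(ds) && !all(is.na(ds))) {
      dos <- t(ds)
    } else {
      gt <- vcfR::extract.gt(v, element = "GT")
      cnt <- vapply(strsplit(as.vector(gt), "[/|]"), function(a) {
        if (length(a) == 0 || all(is.na(a))) NA_real_ else sum(a == "1")
      }, numeric(1))
      dos <- t(matrix(cnt, nrow(gt), ncol(gt)))
    }
    vi <- data.frame(id = fix[, "ID"],
                     chromosome = as.integer(fix[, "CHROM"]),
                     position = as.integer(fix[, "POS"]),
                     effect_allele = fix[, "ALT"],
                     other_allele = fix[, "REF"],
                     stringsAsFactors = FALSE)
    dos <- dos[, !multi, drop = FALSE]
    vi <- vi[!multi, , drop = FALSE]
    colnames(dos) <- vi$id
    rownames(dos) <- NULL
  }
  if (any(dos < -1e-9 | dos > 2 + 1e-9, na.rm = TRUE))
    stop("dosages outside [0, 2]")
  list(dosages = dos, variant_info = vi)
}

#' Write and read the phenotype table
#'
#' Tab-separated, UTF-8, one row per individual, named header columns.
#'
#' @param phenotypes Data frame.
#' @param path File path.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a complete synthetic cohort to a directory
#'
#' Genotypes (dosage TSV or VCF), phenotype TSV, the simulation
#' configuration as YAML, and the simulation log (true parameter values
#' for recovery tests) as JSON.
#'
#' @param cohort An \code{ft_cohort}.
#' @param dir Output directory (created if needed).
#' @param genotype_format "tsv" or "vcf".
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir, genotype_format = c("tsv", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(phenotypes = file.path(dir, "phenotypes.tsv"),
                config = file.path(dir, "config.yaml"),
                sim_log = file.path(dir, "sim_log.json"))
  write_phenotypes_tsv(cohort$phenotypes, paths$phenotypes)
  cfg <- unclass(cohort$config)
  # a length-1 named vector would serialize as a bare scalar; keep the map
  cfg$binary_outcome_prevalences <- as.list(cfg$binary_outcome_prevalences)
  yaml::write_yaml(cfg, paths$config)
  jsonlite::write_json(cohort$sim_log, paths$sim_log, auto_unbox = TRUE,
                       digits = NA)
  if (genotype_format == "tsv") {
    paths$genotypes <- file.path(dir, "dosages.tsv")
    write_dosage_tsv(cohort$dosages, cohort$variant_info, paths$genotypes)
  } else {
    paths$genotypes <- file.path(dir, "genotypes.vcf")
    write_vcf(cohort$dosages, cohort$variant_info, paths$genotypes)
  }
  invisible(paths)
}

#' Read a simulation configuration from YAML
#'
#' Unknown keys are rejected; values are validated by
#' \code{\link{sim_config}}.
#'
#' @param path YAML file.
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$binary_outcome_prevalences))
    raw$binary_outcome_prevalences <- unlist(raw$binary_outcome_prevalences)
  do.call(sim_config, raw)
}
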