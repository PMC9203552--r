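## Plain-text readers/writers for the pipeline's interchange formats.

#' Write / read a phenotype table (TSV)
#'
#' One row per subject; all subject-table columns are preserved, including
#' split and group labels and the clinical metric columns.
#'
#' @param subjects subject tibble (see [generate_cohort()]).
#' @param path file path.
#' @return `read_phenotypes` returns a tibble.
#' @export
write_phenotypes <- function(subjects, path) {
  write.table(subjects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE))
}

#' Write / read an FC panel as a delimited matrix with a subject-ID index
#'
#' @param fc subjects x features matrix with subject-ID rownames.
#' @param path file path.
#' @return `read_fc_panel` returns the matrix with restored rownames.
#' @export
write_fc_panel <- function(fc, path) {
  df <- data.frame(subject_id = rownames(fc), fc, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fc_panel
#' @export
read_fc_panel <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  colnames(m) <- NULL
  m
}

#' Write / read a motion trace as 6-column whitespace-delimited text
#'
#' Column order: dx dy dz rot_x rot_y rot_z, one row per frame (the common
#' realignment-parameter layout).
#'
#' @param trace a [motion_trace()].
#' @param path file path.
#' @param tr frame period passed to the reader.
#' @return `read_motion_trace` returns a [motion_trace()].
#' @export
write_motion_trace <- function(trace, path) {
  write.table(as.data.frame(trace)[, c("dx", "dy", "dz",
                                       "rot_x", "rot_y", "rot_z")],
              path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion_trace
#' @export
read_motion_trace <- function(path, tr = 0.72) {
  m <- as.matrix(read.table(path, header = FALSE))
  motion_trace(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6], tr = tr)
}

#' Write / read a censor mask as 2-column TSV (frame, flag)
#'
#' @param mask a `censor_mask`.
#' @param path file path.
#' @return `read_censor_mask` returns a `censor_mask`.
#' @export
write_censor_mask <- function(mask, path) {
  write.table(data.frame(frame = mask$frame,
                         flag = ifelse(mask$kept, "kept", "censored")),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_censor_mask
#' @export
read_censor_mask <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- tibble::tibble(frame = df$frame, kept = df$flag == "kept")
  structure(out, n_censored = sum(!out$kept), n_kept = sum(out$kept),
            class = c("censor_mask", class(out)))
}

#' Write a genotype panel as VCF 4.2 with GT fields
#'
#' @param dosage subjects x SNPs minor-allele dosage matrix (NA = missing,
#'   written as `./.`).
#' @param snp_info tibble with columns id, chrom, pos, ref, alt.
#' @param path output path (plain text).
#' @return the path, invisibly.
#' @export
write_vcf_panel <- function(dosage, snp_info, path) {
  ids <- rownames(dosage) %||% sprintf("S%04d", seq_len(nrow(dosage)))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  for (j in seq_len(ncol(dosage))) {
    gt <- gt_code[as.character(dosage[, j])]
    gt[is.na(gt)] <- "./."
    writeLines(paste(c(snp_info$chrom[j], snp_info$pos[j], snp_info$id[j],
                       snp_info$ref[j], snp_info$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a genotype panel from VCF
#'
#' Parses GT fields into an alternate-allele dosage matrix via
#' [vcfR::read.vcfR()]; `./.` becomes `NA`.
#'
#' @param path VCF path.
#' @return list with `dosage` (subjects x SNPs) and `snp_info` tibble.
#' @export
read_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c("./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(a) sum(a == "1"), integer(1)))
  }
  dosage <- t(apply(gt, 1, count_alt))
  dosage <- t(dosage)   # subjects x SNPs
  rownames(dosage) <- colnames(gt)
  colnames(dosage) <- rownames(gt)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  list(dosage = dosage,
       snp_info = tibble::tibble(id = fix$ID,
                                 chrom = fix$CHROM,
                                 pos = as.integer(fix$POS),
                                 ref = fix$REF, alt = fix$ALT))
}

#' Write a full synthetic cohort to a directory of plain-text files
#'
#' Writes `phenotypes.tsv`, `fc_scan1.tsv`, `fc_scan2.tsv` and `genotypes.vcf`.
#'
#' @param cohort an `fcb_cohort`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fcb_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phenotypes(cohort$subjects, file.path(dir, "phenotypes.tsv"))
  write_fc_panel(cohort$fc_scan1, file.path(dir, "fc_scan1.tsv"))
  write_fc_panel(cohort$fc_scan2, file.path(dir, "fc_scan2.tsv"))
  write_vcf_panel(cohort$genotypes$dosage, cohort$genotypes$snp_info,
                  file.path(dir, "genotypes.vcf"))
  invisible(dir)
}
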