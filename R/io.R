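#' Write and read pedigree files
#'
#' The pedigree is stored as two CSVs: an offspring file with header
#' `offspring_id,sire_id,dam_id` and a roster file `parent_id,sex`
#' (sex `M`/`F`) listing every spawned parent, including those with no
#' offspring. Write-read-write round trips are byte-identical.
#'
#' @param pedigree a `hatchery_pedigree` (cross structure, if present, is
#'   not serialised).
#' @param offspring_path,roster_path file paths.
#' @return `write_pedigree()` returns the paths invisibly;
#'   `read_pedigree()` returns a `hatchery_pedigree` (with `crosses` and
#'   `config` set to `NULL`).
#' @export
write_pedigree <- function(pedigree, offspring_path, roster_path) {
  write.csv(pedigree$offspring[, c("offspring_id", "sire_id", "dam_id")],
            offspring_path, row.names = FALSE, quote = FALSE)
  write.csv(pedigree$parents[, c("parent_id", "sex")],
            roster_path, row.names = FALSE, quote = FALSE)
  invisible(c(offspring = offspring_path, roster = roster_path))
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(offspring_path, roster_path) {
  off <- read.csv(offspring_path, colClasses = "character")
  ros <- read.csv(roster_path, colClasses = "character")
  need <- c("offspring_id", "sire_id", "dam_id")
  if (!all(need %in% names(off))) {
    stop("offspring file must have columns ", paste(need, collapse = ", "))
  }
  if (!all(c("parent_id", "sex") %in% names(ros))) {
    stop("roster file must have columns parent_id, sex")
  }
  if (!all(ros$sex %in% c("M", "F"))) stop("roster sex must be M or F")
  sex <- setNames(ros$sex, ros$parent_id)
  if (any(sex[off$sire_id] != "M", na.rm = TRUE) ||
      any(sex[off$dam_id] != "F", na.rm = TRUE)) {
    stop("every offspring's sire must be male and dam female")
  }
  if (!all(c(off$sire_id, off$dam_id) %in% ros$parent_id)) {
    stop("offspring reference parents missing from the roster")
  }
  structure(list(parents = ros[, c("parent_id", "sex")],
                 crosses = NULL,
                 offspring = off[, need],
                 config = NULL),
            class = "hatchery_pedigree")
}

#' Write and read genotype tables
#'
#' CSV with header `individual_id,<locus_1>,...,<locus_L>` and cell values
#' 0/1/2 or `NA`.
#'
#' @param genotypes genotype matrix with row names.
#' @param path file path.
#' @return `write_genotypes()` returns `path` invisibly;
#'   `read_genotypes()` returns an integer matrix of class
#'   `genotype_table`.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(individual_id = rownames(genotypes), genotypes,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  if (!all(m %in% c(0L, 1L, 2L) | is.na(m))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  structure(m, class = c("genotype_table", class(m)))
}

#' Write offspring genotypes in two-column-per-locus format
#'
#' Interop writer for external sibship software: one row per individual,
#' two allele columns per locus coded 1/2 with 0 for missing, whitespace
#' separated. Heterozygotes are written as `1 2`.
#'
#' @param genotypes genotype matrix (0/1/2/NA codes).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_colony_genotypes <- function(genotypes, path) {
  n <- nrow(genotypes); L <- ncol(genotypes)
  a1 <- matrix("1", n, L); a2 <- matrix("2", n, L)
  a2[genotypes == 0L] <- "1"
  a1[genotypes == 2L] <- "2"
  a1[is.na(genotypes)] <- "0"; a2[is.na(genotypes)] <- "0"
  cols <- matrix(NA_character_, n, 2 * L)
  cols[, seq(1, 2 * L, by = 2)] <- a1
  cols[, seq(2, 2 * L, by = 2)] <- a2
  lines <- paste(rownames(genotypes), apply(cols, 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Write the pedigree truth summary as JSON
#'
#' Records the true Nb (PwoP on the complete pedigree), the ki histogram,
#' and the true dyad counts.
#'
#' @param pedigree a `hatchery_pedigree`.
#' @param path output JSON file.
#' @return the truth list, invisibly.
#' @export
write_truth <- function(pedigree, path) {
  ki <- ki_vector(pedigree)
  dy <- label_dyads(pedigree)
  truth <- list(
    n_offspring = nrow(pedigree$offspring),
    n_parents = nrow(pedigree$parents),
    n_successful_parents = length(ki),
    true_nb = pwop_nb(ki),
    nb_nc_ratio = pwop_nb(ki) / nrow(pedigree$parents),
    ki_histogram = as.list(table(unclass(ki))),
    dyad_counts = as.list(dy$counts)
  )
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(truth)
}
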