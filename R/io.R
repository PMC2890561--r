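# Plain-text readers and writers: 3x3 count tables and individual-level
# genotype matrices.

#' Write a genotype count table as TSV
#'
#' Format: a metadata comment line `#marker_allele=<M> #disease_allele=<A>`
#' recording allele orientation, a header `.\tAA\tAa\taa`, and three data
#' rows labelled MM, Mm, mm with integer cells.
#'
#' @param counts A [genotype_counts()] table.
#' @param path Output path.
#' @param marker_allele,disease_allele Orientation labels for the counted
#'   alleles.
#' @export
write_count_table <- function(counts, path, marker_allele = "M",
                              disease_allele = "A") {
  counts <- genotype_counts(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#marker_allele=%s #disease_allele=%s",
                     marker_allele, disease_allele), con)
  writeLines(paste(c(".", .DISEASE_GT), collapse = "\t"), con)
  for (i in 1:3)
    writeLines(paste(c(.MARKER_GT[i], format(counts[i, ], trim = TRUE,
                                             scientific = FALSE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a genotype count table from TSV
#'
#' Inverse of [write_count_table()]. Cells must be non-negative integers;
#' malformed input raises a parse error naming the offending line.
#'
#' @param path Input path.
#' @return A [genotype_counts()] table with attributes `marker_allele` and
#'   `disease_allele` when the metadata line is present.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- list(marker_allele = NA_character_, disease_allele = NA_character_)
  if (length(lines) && startsWith(lines[1], "#")) {
    mm <- regmatches(lines[1],
                     regexec("#marker_allele=(\\S+)\\s+#disease_allele=(\\S+)",
                             lines[1]))[[1]]
    if (length(mm) == 3) {
      meta$marker_allele <- mm[2]; meta$disease_allele <- mm[3]
    }
    lines <- lines[-1]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 4)
    stop("count table must have a header plus 3 data rows, found ",
         length(lines), " lines", call. = FALSE)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 4 || !identical(hdr[2:4], .DISEASE_GT))
    stop("count table header must be '.\tAA\tAa\taa' (line 1): ", lines[1],
         call. = FALSE)
  x <- matrix(NA_real_, 3, 3)
  for (i in 1:3) {
    fields <- strsplit(lines[i + 1], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 4 || fields[1] != .MARKER_GT[i])
      stop(sprintf("count table row %d must be labelled %s: %s",
                   i, .MARKER_GT[i], lines[i + 1]), call. = FALSE)
    vals <- suppressWarnings(as.numeric(fields[2:4]))
    bad <- which(!is.finite(vals) | vals < 0 | vals != round(vals))
    if (length(bad))
      stop(sprintf("row %s, column %s: cell '%s' is not a non-negative integer",
                   .MARKER_GT[i], .DISEASE_GT[bad[1]], fields[1 + bad[1]]),
           call. = FALSE)
    x[i, ] <- vals
  }
  out <- genotype_counts(x)
  attr(out, "marker_allele") <- meta$marker_allele
  attr(out, "disease_allele") <- meta$disease_allele
  out
}

#' Individual-level genotype matrix
#'
#' Constructor for genotype panels: per-individual, per-locus codes
#' counting copies of the designated allele (0/1/2, `NA` for missing), with
#' optional case/control labels. Codes never use a minor-allele convention:
#' the designated allele is whatever the file's column orientation says,
#' because the sign of D depends on it.
#'
#' @param codes Integer matrix (individuals x loci) with values 0, 1, 2 or
#'   NA; must have unique column (locus) names.
#' @param ids Individual identifiers (default from rownames or generated).
#' @param labels Optional per-individual labels `"case"`/`"control"`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, ids = NULL, labels = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(colnames(codes)) || anyDuplicated(colnames(codes)))
    stop("locus names must be present and unique", call. = FALSE)
  if (any(!codes %in% c(0L, 1L, 2L, NA_integer_)))
    stop("genotype codes must be 0, 1, 2 or missing", call. = FALSE)
  if (is.null(ids)) ids <- rownames(codes) %||% paste0("ind", seq_len(nrow(codes)))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(codes) ||
        !all(labels %in% c("case", "control")))
      stop("labels must be 'case'/'control', one per individual", call. = FALSE)
  }
  rownames(codes) <- ids
  miss <- colMeans(is.na(codes))
  if (any(miss == 1))
    warning("loci with all genotypes missing: ",
            paste(colnames(codes)[miss == 1], collapse = ", "))
  structure(list(codes = codes, ids = ids, loci = colnames(codes),
                 labels = labels, missingness = miss),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d loci%s\n",
              nrow(x$codes), ncol(x$codes),
              if (!is.null(x$labels))
                sprintf(" (%d cases, %d controls)",
                        sum(x$labels == "case"), sum(x$labels == "control"))
              else ""))
  invisible(x)
}

#' Read an individual-level genotype matrix from TSV
#'
#' Expected layout: header `id [status] locus1 locus2 ...`; one row per
#' individual; codes 0/1/2 count copies of the designated allele, `.` marks
#' a missing genotype. The optional `status` column holds `case`/`control`.
#'
#' @param path Input path.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "#")
  if (!identical(colnames(df)[1], "id"))
    stop("first column must be 'id'", call. = FALSE)
  labels <- NULL
  first_locus <- 2L
  if (ncol(df) >= 2 && colnames(df)[2] == "status") {
    labels <- df[[2]]
    first_locus <- 3L
  }
  if (ncol(df) < first_locus) stop("no locus columns found", call. = FALSE)
  loci <- colnames(df)[first_locus:ncol(df)]
  if (anyDuplicated(loci))
    stop("duplicated locus name(s): ",
         paste(unique(loci[duplicated(loci)]), collapse = ", "), call. = FALSE)
  raw <- as.matrix(df[, first_locus:ncol(df), drop = FALSE])
  bad <- matrix(!(raw %in% c("0", "1", "2", ".")), nrow(raw))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype code '%s' for individual %s, locus %s (allowed: 0 1 2 .)",
                 raw[w[1], w[2]], df$id[w[1]], loci[w[2]]), call. = FALSE)
  }
  codes <- matrix(NA_integer_, nrow(raw), ncol(raw),
                  dimnames = list(df$id, loci))
  codes[raw != "."] <- as.integer(raw[raw != "."])
  genotype_matrix(codes, ids = df$id, labels = labels)
}

#' Write a genotype matrix as TSV (round-trip inverse of the reader)
#'
#' @param x A [genotype_matrix()].
#' @param path Output path.
#' @export
write_genotype_matrix <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  chr <- matrix(as.character(x$codes), nrow(x$codes))
  chr[is.na(chr)] <- "."
  df <- data.frame(id = x$ids, stringsAsFactors = FALSE)
  if (!is.null(x$labels)) df$status <- x$labels
  df <- cbind(df, as.data.frame(chr, stringsAsFactors = FALSE))
  colnames(df) <- c("id", if (!is.null(x$labels)) "status", x$loci)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
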