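#' Read a gene x sample expression matrix (plain TSV or GCT 1.2)
#'
#' TSV layout: header row of sample ids, first column gene ids. GCT 1.2:
#' `#1.2` version line, a dimensions line, then `Name`/`Description` columns
#' before the samples. Non-numeric cells become `NA`. Gene ids are matched
#' case-sensitively after whitespace trimming; duplicate gene ids are kept
#' (collapse them with [collapse_duplicate_genes()]), duplicate sample ids
#' are a format error.
#'
#' @param path File path.
#' @param format `"auto"` (by extension / `#1.2` sniff), `"tsv"` or `"gct"`.
#' @return Numeric matrix with gene-id rownames and sample-id colnames.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^#1\\.", first) || grepl("\\.gct$", path,
                                                 ignore.case = TRUE))
      "gct" else "tsv"
  }
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || !identical(trimws(lines[1L]), "#1.2"))
      stop("GCT format error: missing '#1.2' version line")
    dims <- as.integer(strsplit(trimws(lines[2L]), "\t")[[1]][1:2])
    if (any(is.na(dims))) stop("GCT format error: bad dimensions line")
    body <- utils::read.delim(text = lines[-(1:2)], header = TRUE,
                              check.names = FALSE, colClasses = "character")
    if (ncol(body) < 3L) stop("GCT format error: need Name, Description, samples")
    if (nrow(body) != dims[1L] || ncol(body) - 2L != dims[2L])
      stop(sprintf(
        "GCT format error: header declares %d x %d but file has %d x %d",
        dims[1L], dims[2L], nrow(body), ncol(body) - 2L))
    ids <- trimws(body[[1L]])
    samples <- trimws(colnames(body)[-(1:2)])
    vals <- body[-(1:2)]
  } else {
    body <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                              colClasses = "character")
    ids <- trimws(body[[1L]])
    samples <- trimws(colnames(body)[-1L])
    vals <- body[-1L]
  }
  if (anyDuplicated(samples))
    stop("format error: duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  x <- matrix(suppressWarnings(as.numeric(as.matrix(vals))),
              nrow = length(ids), dimnames = list(ids, samples))
  if (anyDuplicated(ids))
    message(sum(duplicated(ids)),
            " duplicate gene id row(s); see collapse_duplicate_genes()")
  x
}

#' Write an expression matrix as TSV or GCT 1.2
#'
#' Values are written with 15 significant digits so write -> read round
#' trips are lossless well beyond 6 significant digits. UTF-8, LF endings.
#'
#' @param x Numeric gene x sample matrix with dimnames.
#' @param path Output path.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  fmt <- function(v) ifelse(is.na(v), "NA", format(v, digits = 15,
                                                   trim = TRUE,
                                                   scientific = NA))
  rows <- apply(x, 1L, function(v) paste(fmt(v), collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(s) writeLines(s, con, sep = "\n", useBytes = TRUE)
  if (format == "gct") {
    wl("#1.2")
    wl(paste(nrow(x), ncol(x), sep = "\t"))
    wl(paste(c("Name", "Description", colnames(x)), collapse = "\t"))
    wl(paste(rownames(x), "na", rows, sep = "\t"))
  } else {
    wl(paste(c("gene", colnames(x)), collapse = "\t"))
    wl(paste(rownames(x), rows, sep = "\t"))
  }
  invisible(path)
}

#' Collapse duplicate gene rows to their per-sample mean
#'
#' Rows sharing a gene id are replaced by their arithmetic per-sample mean,
#' ignoring missing values cell-wise (a cell that is missing in every
#' duplicate stays `NA`). Output row order is the first occurrence of each
#' gene id.
#'
#' @param x Numeric gene x sample matrix with rownames.
#' @return Matrix with unique rownames.
#' @examples
#' m <- rbind(A = c(1, 3), A = c(3, 5), B = c(0, 1))
#' colnames(m) <- c("s1", "s2")
#' collapse_duplicate_genes(m)
#' @export
collapse_duplicate_genes <- function(x) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  ids <- rownames(x)
  if (!anyDuplicated(ids)) return(x)
  f <- factor(ids, levels = unique(ids))
  cnt <- rowsum(1 - is.na(x), f, reorder = FALSE)
  tot <- rowsum(ifelse(is.na(x), 0, x), f, reorder = FALSE)
  out <- tot / cnt   # 0/0 -> NaN where all duplicates missing
  out[cnt == 0] <- NA_real_
  rownames(out) <- levels(f)
  out
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#' Duplicate genes within a set are dropped with a warning; an effectively
#' empty set or a line with fewer than 3 fields is a format error.
#'
#' @param path File path.
#' @return `read_gmt`: a named list of unique gene-id character vectors,
#'   with a `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character()
  for (ln in lines) {
    parts <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (length(parts) < 3L)
      stop("GMT format error: line with fewer than 3 fields: ",
           substr(ln, 1, 60))
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in set '", parts[1L], "' deduplicated")
      genes <- unique(genes)
    }
    if (!length(genes)) stop("GMT format error: empty set '", parts[1L], "'")
    if (parts[1L] %in% names(sets))
      stop("GMT format error: duplicate set name '", parts[1L], "'")
    sets[[parts[1L]]] <- genes
    desc[parts[1L]] <- parts[2L]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene-id vectors (optionally with a
#'   `descriptions` attribute).
#' @return `write_gmt`: `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- attr(sets, "descriptions")
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in names(sets)) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    writeLines(paste(c(nm, d, sets[[nm]]), collapse = "\t"), con,
               sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a clinical survival table
#'
#' Tab-separated with a header; required columns `sample`, `time` (days),
#' `event` (0/1). Optional columns `age`, `gcimp`, `radiotherapy`,
#' `temozolomide`, `subtype` are typed when present. Rows with missing time
#' or event are dropped with a message; a negative time or a non-binary
#' event value is an error naming the offending sample.
#'
#' @param path File path.
#' @return data.frame, one row per retained sample.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  required <- c("sample", "time", "event")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(d$sample))
    stop("format error: duplicate sample ids")
  d$time <- suppressWarnings(as.numeric(d$time))
  d$event <- suppressWarnings(as.numeric(d$event))
  drop <- is.na(d$time) | is.na(d$event)
  if (any(drop)) {
    message("dropping ", sum(drop), " sample(s) missing time or event")
    d <- d[!drop, , drop = FALSE]
  }
  if (any(d$time < 0))
    stop("format error: negative survival time for sample(s): ",
         paste(d$sample[d$time < 0], collapse = ", "))
  if (!all(d$event %in% c(0, 1)))
    stop("format error: non-binary event value for sample(s): ",
         paste(d$sample[!d$event %in% c(0, 1)], collapse = ", "))
  d$event <- as.integer(d$event)
  for (col in c("age", "gcimp", "radiotherapy", "temozolomide"))
    if (col %in% names(d)) d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  rownames(d) <- NULL
  d
}

#' @rdname read_clinical
#' @param d Clinical data.frame as returned by [read_clinical()] or
#'   [simulate_clinical()].
#' @return `write_clinical`: `path`, invisibly.
#' @export
write_clinical <- function(d, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
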