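#' Construct a set of genomic intervals
#'
#' Intervals are stored 0-based half-open (BED convention) in a plain
#' `data.frame` with columns `chrom`, `start`, `end`, `name`, `score`,
#' `strand` and `summit_offset`. All functions in the package that accept
#' peak sets take this layout.
#'
#' @param chrom character vector of chromosome names (compared exactly;
#'   no "chr" aliasing unless `normalize_chrom()` is applied explicitly).
#' @param start,end integer vectors, 0-based half-open; `end > start`.
#' @param name optional feature names.
#' @param score optional numeric scores.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @param summit_offset optional integer offset of the peak summit from
#'   `start`, in `[0, end - start)`.
#' @return a `data.frame` of intervals.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = ".",
                              summit_offset = NA_integer_) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    strand = rep_len(as.character(strand), n),
    summit_offset = rep_len(as.integer(summit_offset), n),
    stringsAsFactors = FALSE
  )
  check_intervals(df)
  df
}

check_intervals <- function(df, what = "interval set") {
  stopifnot(is.data.frame(df))
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$start < 0)) stop(what, ": negative start coordinate")
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(what, ": end <= start at row(s) ", paste(head(bad, 5), collapse = ", "))
  if (!is.null(df$strand) && !all(df$strand %in% c("+", "-", ".")))
    stop(what, ": strand must be one of '+', '-', '.'")
  if (!is.null(df$summit_offset)) {
    so <- df$summit_offset
    ok <- is.na(so) | (so >= 0 & so < df$end - df$start)
    if (!all(ok))
      stop(what, ": summit_offset outside [0, width) at row(s) ",
           paste(head(which(!ok), 5), collapse = ", "))
  }
  invisible(df)
}

#' Read a BED / narrowPeak file into genomic intervals
#'
#' Accepts BED3, BED6 and 10-column narrowPeak. The narrowPeak summit column
#' (10th, 0-based offset from `start`; `-1` for "no summit") is mapped to
#' `summit_offset`.
#'
#' @param path path to a tab-separated BED-dialect file.
#' @return intervals as produced by [genomic_intervals()], in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 columns")
  ncol_use <- min(nf)
  get <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-integer coordinates")
  inv <- which(end <= start)
  if (length(inv))
    stop("invalid interval on line ", inv[1], ": end <= start")
  name <- if (ncol_use >= 4) get(4) else NA_character_
  score <- if (ncol_use >= 5) suppressWarnings(as.numeric(get(5))) else NA_real_
  strand <- if (ncol_use >= 6) get(6) else "."
  summit <- NA_integer_
  if (ncol_use >= 10) {
    summit <- suppressWarnings(as.integer(get(10)))
    summit[!is.na(summit) & summit < 0] <- NA_integer_
  }
  genomic_intervals(get(1), start, end, name = name, score = score,
                    strand = strand, summit_offset = summit)
}

#' Write genomic intervals as BED / narrowPeak
#'
#' Emits BED3 when only coordinates are present, BED6 when names/scores/strand
#' are present, and 10-column narrowPeak when any `summit_offset` is set
#' (placeholder `0` for signalValue/pValue/qValue; `-1` for absent summits),
#' so that `read_bed(write_bed(x))` reproduces coordinates, scores and summits.
#'
#' @param x intervals (see [genomic_intervals()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  has_meta <- any(!is.na(x$name)) || any(!is.na(x$score)) ||
    any(x$strand != ".")
  has_summit <- "summit_offset" %in% names(x) && any(!is.na(x$summit_offset))
  fmt_num <- function(v) ifelse(is.na(v), ".", format(v, trim = TRUE,
                                                     scientific = FALSE))
  cols <- list(x$chrom, x$start, x$end)
  if (has_meta || has_summit) {
    cols <- c(cols, list(ifelse(is.na(x$name), ".", x$name),
                         fmt_num(x$score), x$strand))
  }
  if (has_summit) {
    so <- x$summit_offset
    cols <- c(cols, list(0, 0, 0, ifelse(is.na(so), -1L, so)))
  }
  tab <- do.call(cbind, lapply(cols, as.character))
  writeLines(apply(tab, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read gene models (GTF-lite or tab-separated gene table)
#'
#' Two dialects are supported: a 9-column GTF restricted to `gene` records
#' (1-based closed coordinates, converted on read) and a headered TSV with
#' columns `gene_id`, `chrom`, `start`, `end`, `strand` (0-based half-open).
#' The TSS is derived from the strand: `start` on `+`, `end - 1` on `-`.
#'
#' @param path input file.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `body_start`, `body_end`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  nfields <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (nfields == 9 && !grepl("gene_id\tchrom", first)) {
    gtf <- read.table(path, sep = "\t", header = FALSE, quote = "",
                      comment.char = "#", stringsAsFactors = FALSE)
    gtf <- gtf[gtf[[3]] == "gene", , drop = FALSE]
    if (!nrow(gtf)) stop("no gene records in GTF: ", path)
    ids <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", gtf[[9]])
    gm <- data.frame(gene_id = ids, chrom = as.character(gtf[[1]]),
                     start = as.integer(gtf[[4]]) - 1L,
                     end = as.integer(gtf[[5]]),
                     strand = as.character(gtf[[7]]),
                     stringsAsFactors = FALSE)
  } else {
    gm <- read.table(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    req <- c("gene_id", "chrom", "start", "end", "strand")
    miss <- setdiff(req, names(gm))
    if (length(miss))
      stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  }
  gene_models(gm$gene_id, gm$chrom, gm$start, gm$end, gm$strand)
}

#' Construct gene models from body coordinates and strand
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param body_start,body_end gene body, 0-based half-open.
#' @param strand `"+"` or `"-"` (TSS at `body_start` resp. `body_end - 1`).
#' @return `data.frame` with `gene_id`, `chrom`, `tss`, `strand`,
#'   `body_start`, `body_end`.
#' @export
gene_models <- function(gene_id, chrom, body_start, body_end, strand) {
  gene_id <- as.character(gene_id)
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup))
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop("unknown strand value; gene strand must be '+' or '-'")
  body_start <- as.integer(body_start)
  body_end <- as.integer(body_end)
  if (any(body_end <= body_start)) stop("gene body end <= start")
  data.frame(
    gene_id = gene_id, chrom = as.character(chrom),
    tss = ifelse(strand == "+", body_start, body_end - 1L),
    strand = as.character(strand),
    body_start = body_start, body_end = body_end,
    stringsAsFactors = FALSE
  )
}

#' Construct a count table
#'
#' @param counts numeric matrix, features in rows, samples in columns; finite
#'   and non-negative, with unique dimnames.
#' @return list with `counts` and `lib_sizes` (column sums), class
#'   `count_table`.
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!nrow(counts) || !ncol(counts)) stop("empty count table")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table needs row and column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate row ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate column ids")
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0)) stop("negative counts")
  structure(list(counts = counts, lib_sizes = colSums(counts)),
            class = "count_table")
}

#' Read a count table from TSV
#'
#' First column holds feature ids, header holds sample ids.
#'
#' @param path input TSV.
#' @return a [count_table()].
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (ncol(raw) < 2) stop("count table needs id column plus >= 1 sample")
  if (!nrow(raw)) stop("empty count table")
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!apply(raw[, -1, drop = FALSE], 2,
                        function(v) all(grepl("^\\s*-?[0-9.eE+-]+\\s*$", v))))
    cellcol <- names(raw)[-1][bad[1]]
    cellrow <- which(is.na(suppressWarnings(
      as.numeric(raw[[bad[1] + 1]]))))[1]
    stop("non-numeric value in column '", cellcol, "', row ",
         ifelse(is.na(cellrow), "?", cellrow))
  }
  rownames(mat) <- ids
  count_table(mat)
}

#' Write a count table as TSV
#' @param x a [count_table()] or matrix with dimnames.
#' @param path output path.
#' @param id_col name of the leading id column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, id_col = "feature_id") {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read single-cell counts from MatrixMarket sidecar files
#'
#' @param mtx path to the MTX matrix (features in rows or columns as written).
#' @param row_ids,col_ids paths to one-id-per-line sidecar files for rows and
#'   columns of the MTX.
#' @return dense count matrix with dimnames.
#' @export
read_mtx_counts <- function(mtx, row_ids, col_ids) {
  m <- as.matrix(Matrix::readMM(mtx))
  rn <- readLines(row_ids)
  cn <- readLines(col_ids)
  if (nrow(m) != length(rn) || ncol(m) != length(cn))
    stop("MTX dimensions do not match sidecar id files")
  dimnames(m) <- list(rn, cn)
  m
}

#' Strip a leading "chr" prefix from chromosome names
#'
#' Chromosome names are otherwise compared exactly throughout the package;
#' apply this explicitly (to both operands) when mixing dialects.
#'
#' @param chrom character vector.
#' @return normalized names.
#' @export
normalize_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

interval_center <- function(x) (x$start + x$end) %/% 2L

interval_anchor <- function(x) {
  a <- interval_center(x)
  if ("summit_offset" %in% names(x)) {
    has <- !is.na(x$summit_offset)
    a[has] <- x$start[has] + x$summit_offset[has]
  }
  a
}
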