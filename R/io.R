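## Reading and writing the package's plain-text interchange formats:
## read sets (plain text / FASTA / FASTQ, gzip-transparent), k-mer tables,
## and k-mer model files.

open_text_conn <- function(path) {
  if (grepl("\\.gz$", path, ignore.case = TRUE)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a set of sequence reads
#'
#' Reads plain text (one read per line), FASTA or FASTQ (qualities ignored).
#' The format is inferred from the file extension, falling back to peeking at
#' the first character. Gzip-compressed files are handled transparently.
#' Sequences are uppercased on ingestion.
#'
#' @param path Path to the read file.
#' @param format `"auto"` (default), `"txt"`, `"fasta"` or `"fastq"`.
#' @return Character vector of reads.
#' @export
read_reads <- function(path, format = c("auto", "txt", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bz2|xz)$", "", path, ignore.case = TRUE)
    ext <- tolower(tools::file_ext(base))
    format <- if (ext %in% c("fa", "fasta", "fna")) "fasta"
    else if (ext %in% c("fq", "fastq")) "fastq"
    else "peek"
    if (format == "peek") {
      con <- open_text_conn(path)
      first <- readLines(con, n = 1L)
      close(con)
      format <- if (length(first) && startsWith(first, ">")) "fasta"
      else if (length(first) && startsWith(first, "@")) "fastq"
      else "txt"
    }
  }
  reads <- switch(format,
    txt = {
      con <- open_text_conn(path)
      on.exit(close(con))
      x <- readLines(con)
      x[nzchar(trimws(x))]
    },
    fasta = as.character(Biostrings::readDNAStringSet(path, format = "fasta")),
    fastq = as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  )
  unname(normalize_seqs(reads))
}

#' Write a set of sequence reads
#'
#' @param reads Character vector of reads.
#' @param path Output path.
#' @param format `"txt"` (one read per line) or `"fasta"`.
#' @param names Optional record names for FASTA output; defaults to
#'   `read_1 ... read_n`.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, format = c("txt", "fasta"), names = NULL) {
  format <- match.arg(format)
  reads <- normalize_seqs(reads)
  if (format == "txt") {
    writeLines(reads, path)
  } else {
    if (is.null(names)) names <- paste0("read_", seq_along(reads))
    dss <- Biostrings::DNAStringSet(reads)
    names(dss) <- names
    Biostrings::writeXStringSet(dss, path)
  }
  invisible(path)
}

#' Export a k-mer table as TSV
#'
#' Writes columns `kmer`, `k`, `count_bound`, `count_unbound`, `difference`
#' and `fold_change`. Fold change uses a pseudocount on both counts so that
#' k-mers absent from the unbound set remain finite.
#'
#' @param table A `kmer_table` from [build_kmer_table()].
#' @param path Output path.
#' @param pseudocount Pseudocount used in the fold-change column (default 1).
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path, pseudocount = 1) {
  stopifnot(inherits(table, "kmer_table"))
  df <- as.data.frame(table)
  df$difference <- df$count_bound - df$count_unbound
  df$fold_change <- (df$count_bound + pseudocount) / (df$count_unbound + pseudocount)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_full <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

parse_num <- function(x, integer = FALSE) {
  if (x %in% c("NA", "nan", "-nan")) return(if (integer) NA_integer_ else NA_real_)
  if (integer) as.integer(x) else as.numeric(x)
}

#' Save a k-mer model to a TSV file
#'
#' The file carries a small `# key=value` header (k values, strand handling,
#' ridge penalty, training metadata) followed by `kmer<TAB>affinity` rows.
#' Affinities are serialized at full double precision so that
#' [load_kmer_model()] round-trips losslessly.
#'
#' @param model A `kmer_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_kmer_model <- function(model, path) {
  stopifnot(inherits(model, "kmer_model"))
  lines <- c(
    sprintf("# k_values=%s", paste(model$spec$k, collapse = ",")),
    sprintf("# canonicalize=%s", model$spec$canonicalize),
    sprintf("# both_strands=%s", model$spec$both_strands),
    sprintf("# ridge_lambda=%s", format_full(model$ridge_lambda)),
    sprintf("# n_reads=%s", as.character(model$meta$n_reads)),
    sprintf("# residual_norm=%s", format_full(model$meta$residual_norm)),
    "kmer\taffinity",
    sprintf("%s\t%s", model$kmers, format_full(unname(model$affinities)))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Load a k-mer model saved by [save_kmer_model()]
#'
#' @param path Path to a model TSV.
#' @return A `kmer_model`.
#' @export
load_kmer_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_field <- function(key) {
    hit <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (!length(hit)) stop("model file missing header field: ", key)
    sub(paste0("^#\\s*", key, "="), "", hit[1])
  }
  spec <- kmer_spec(
    k = as.integer(strsplit(get_field("k_values"), ",")[[1]]),
    canonicalize = as.logical(get_field("canonicalize")),
    both_strands = as.logical(get_field("both_strands"))
  )
  body <- body[nzchar(body)]
  if (!length(body) || body[1] != "kmer\taffinity") {
    stop("malformed model file: expected 'kmer<TAB>affinity' column header")
  }
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  kmers <- vapply(rows, `[[`, "", 1L)
  aff <- as.numeric(vapply(rows, `[[`, "", 2L))
  new_kmer_model(kmers, aff,
                 ridge_lambda = parse_num(get_field("ridge_lambda")),
                 spec = spec,
                 meta = list(n_reads = parse_num(get_field("n_reads"), integer = TRUE),
                             residual_norm = parse_num(get_field("residual_norm"))))
}

#' Export a selection trajectory as TSV
#'
#' Writes `step`, `removed_kmer`, `remaining_size`, `cv_accuracy`, suitable
#' for plotting accuracy-versus-model-size curves.
#'
#' @param trajectory A `selection_trajectory` from [cv_backward_eliminate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "selection_trajectory"))
  utils::write.table(as.data.frame(trajectory), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an evaluation result
#'
#' @param x An `eval_result`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_eval_result <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "eval_result"))
  df <- as.data.frame(x)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(as.list(df), path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}
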