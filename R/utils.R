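#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based, half-open [start, end), genomic
# (plus-strand) axis. GTF input/output is converted at the boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded helpers do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Reverse-complement a nucleotide string
#' @param x character scalar over A/C/G/T (case preserved as upper).
#' @return character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Slice a genome sequence in 0-based half-open coordinates
#' @noRd
genome_slice <- function(genome, chrom, start0, end0) {
  seq <- genome[[chrom]]
  if (is.null(seq)) stop("chromosome not found in genome: ", chrom)
  start0 <- max(0L, start0)
  end0 <- min(length(seq), end0)
  if (end0 <= start0) return("")
  as.character(Biostrings::subseq(seq, start0 + 1L, end0))
}

#' Read a genome FASTA into a named DNAStringSet
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] keyed by sequence name.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read/write plain TSV with stable conventions
#' @noRd
read_tsv_file <- function(path, required = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss)) {
      stop("file ", path, " is missing required columns: ",
           paste(miss, collapse = ", "))
    }
  }
  df
}

#' @noRd
write_tsv_file <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a splicing-factor motif table
#'
#' Expected columns: `factor`, `motif` (ACGT string), `score` (signed real).
#' Positive-score motifs act as exonic splicing enhancers (ESEs), negative
#' ones as silencers (ESSs).
#' @param path TSV file.
#' @return data.frame with columns factor, motif, score.
#' @export
read_motif_table <- function(path) {
  df <- read_tsv_file(path, required = c("factor", "motif", "score"))
  if (any(nchar(df$motif) == 0L)) stop("motif table contains empty motifs")
  if (any(grepl("[^ACGT]", df$motif))) {
    stop("motif table contains non-ACGT motifs")
  }
  df
}

#' Read a two-species gene homology table
#' @param path TSV with columns gene_id_A, gene_id_B.
#' @return data.frame.
#' @export
read_homology_table <- function(path) {
  read_tsv_file(path, required = c("gene_id_A", "gene_id_B"))
}

#' Read a sample design table
#'
#' Columns: `sample`, `condition` (control vs treatment labels), `replicate`
#' and optionally `library_size` (total mapped reads per sample, used for
#' RPK30M normalisation).
#' @param path TSV file.
#' @return data.frame.
#' @export
read_design <- function(path) {
  df <- read_tsv_file(path, required = c("sample", "condition", "replicate"))
  if (anyDuplicated(df$sample)) stop("duplicate sample names in design")
  df
}
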