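RNA_BASES <- c("A", "C", "G", "U")

#' Construct an RNA window
#'
#' An RNA window is a fixed-length fragment over the alphabet \{A,C,G,U\}
#' whose central base is the candidate adenosine. All feature encodings in
#' this package operate on such windows.
#'
#' @param seq Character scalar, the window sequence.
#' @param id Character scalar identifier.
#' @param label One of `"positive"`, `"negative"`, `"unlabeled"`.
#' @return An object of class `rna_window` with fields `id`, `seq`, `label`.
#' @seealso [validate_window()] which checks the window invariants.
#' @export
rna_window <- function(seq, id = "window", label = "unlabeled") {
  label <- match.arg(label, c("positive", "negative", "unlabeled"))
  structure(list(id = as.character(id), seq = as.character(seq),
                 label = label),
            class = "rna_window")
}

#' @export
print.rna_window <- function(x, ...) {
  cat(sprintf("<rna_window> %s [%s], %d nt\n  %s\n",
              x$id, x$label, nchar(x$seq), x$seq))
  invisible(x)
}

normalize_rna <- function(seq) {
  seq <- toupper(gsub("[[:space:]]", "", seq))
  gsub("T", "U", seq, fixed = TRUE)
}

#' Read RNA sequences from a FASTA file
#'
#' Sequences are uppercased and DNA-style `T` is transcribed to `U`;
#' wrapped and unwrapped records are both accepted.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` (full header line) and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- normalize_rna(as.character(set))
  if (any(nchar(seqs) == 0L)) stop("FASTA record with empty sequence in ", path)
  data.frame(id = names(set), seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Validate a sequence as an RNA window
#'
#' Checks the three window invariants: length equals `W` (odd), every
#' symbol is in \{A,C,G,U\} (after T to U transcription), and the central
#' position holds an adenosine.
#'
#' @param seq Character scalar sequence.
#' @param W Odd window length; default 41.
#' @param id,label Passed through to [rna_window()].
#' @return An `rna_window`, or an error describing the violated invariant.
#' @export
validate_window <- function(seq, W = 41L, id = "window", label = "unlabeled") {
  if (W %% 2L != 1L) stop("window length W must be odd, got ", W)
  seq <- normalize_rna(seq)
  if (nchar(seq) != W)
    stop("window length ", nchar(seq), " != W = ", W)
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(bases), RNA_BASES)
  if (length(bad))
    stop("invalid symbol(s) in window: ", paste(bad, collapse = ", "))
  center <- (W + 1L) / 2L
  if (bases[center] != "A")
    stop("central base must be A, found ", bases[center],
         " at position ", center)
  rna_window(seq, id = id, label = label)
}

#' Encode a window as integer base codes
#'
#' Fixed bijection A=1, C=2, G=3, U=4 (alphabetical over the RNA
#' alphabet). Moment values depend on this mapping, so it is frozen.
#'
#' @param window An `rna_window` or character scalar of valid bases.
#' @return Integer vector of codes in 1..4.
#' @export
encode_bases <- function(window) {
  seq <- if (inherits(window, "rna_window")) window$seq else window
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  codes <- match(bases, RNA_BASES)
  if (anyNA(codes)) stop("sequence contains symbols outside {A,C,G,U}")
  codes
}

#' Decode integer base codes back to a sequence
#' @param codes Integer vector in 1..4.
#' @return Character scalar sequence.
#' @export
decode_bases <- function(codes) {
  stopifnot(all(codes %in% 1:4))
  paste(RNA_BASES[codes], collapse = "")
}

#' Reverse a window's base order
#'
#' Plain order reversal (no complementation); used by the reverse-direction
#' feature groups (RPRIM, RAAPIV).
#'
#' @param window An `rna_window` or character scalar.
#' @return Same type as the input, sequence reversed.
#' @export
reverse_window <- function(window) {
  rev1 <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                            collapse = "")
  if (inherits(window, "rna_window")) {
    window$seq <- rev1(window$seq)
    window
  } else {
    rev1(window)
  }
}

#' Enumerate candidate adenosine sites in a sequence
#'
#' Every `A` whose flanks of (W-1)/2 bases fit entirely inside the
#' sequence yields one window; this is how arbitrary-length inputs are
#' scanned at prediction time.
#'
#' @param seq Character scalar raw sequence (T allowed, transcribed to U).
#' @param W Odd window length.
#' @param id Identifier prefix for the extracted windows.
#' @return A list of entries `list(position =, window =)`, positions
#'   1-based on the input sequence. Empty (with a warning) if the
#'   sequence is shorter than `W`.
#' @export
scan_sites <- function(seq, W = 41L, id = "seq") {
  if (W %% 2L != 1L) stop("window length W must be odd, got ", W)
  seq <- normalize_rna(seq)
  L <- nchar(seq)
  if (L < W) {
    warning("sequence shorter than window length; no sites scanned")
    return(list())
  }
  flank <- (W - 1L) / 2L
  bases <- strsplit(seq, "", fixed = TRUE)[[1L]]
  centers <- which(bases == "A")
  centers <- centers[centers > flank & centers <= L - flank]
  lapply(centers, function(p) {
    sub <- substr(seq, p - flank, p + flank)
    list(position = p,
         window = validate_window(sub, W = W,
                                  id = sprintf("%s:%d", id, p)))
  })
}
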