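# Synthetic labelled 41-nt windows emulating the compositional
# structure of the real m1A data: U/A-rich background, C confined to a
# narrow band around the centre, central A fixed, and a tunable planted
# dinucleotide signal separating the classes.

#' Default per-position base composition profile
#'
#' Rows are window positions, columns A/C/G/U probabilities. The
#' background is U/A-enriched with G flat; C appears only in the band
#' two positions either side of the centre (positions 19-23 for W=41);
#' the central row forces A.
#'
#' @param W Odd window length (default 41).
#' @return A W x 4 matrix of probabilities, rows summing to 1.
#' @export
default_profile <- function(W = 41L) {
  if (W %% 2L != 1L) stop("window length W must be odd, got ", W)
  center <- (W + 1L) / 2L
  prof <- matrix(rep(c(A = 0.35, C = 0, G = 0.20, U = 0.45), each = W),
                 nrow = W, dimnames = list(NULL, RNA_BASES))
  band <- intersect(seq_len(W), (center - 2L):(center + 2L))
  prof[band, ] <- matrix(rep(c(0.30, 0.25, 0.15, 0.30), each = length(band)),
                         nrow = length(band))
  prof[center, ] <- c(1, 0, 0, 0)
  prof
}

# anchor starts for the planted positive-class dinucleotide, upstream of
# the centre at every other position so plants never overlap
signal_anchors <- function(W) {
  center <- (W + 1L) / 2L
  from <- max(1L, center - 12L)
  seq(from, center - 2L, by = 2L)
}

#' Generate labelled synthetic m1A windows
#'
#' Draws each position independently from the composition profile; in
#' positive windows a signal dinucleotide (default "AG") is additionally
#' planted at each of a set of disjoint upstream anchor slots with
#' probability 1 - exp(-effect/2), so `effect = 0` makes the classes
#' exchangeable and larger effects plant a positional and compositional
#' signal that the incidence-matrix features can pick up.
#'
#' @param n_pos,n_neg Number of positive / negative windows.
#' @param W Odd window length (default 41).
#' @param effect Nonnegative signal strength; 0 means no class signal.
#' @param seed Integer seed; generation is deterministic in it.
#' @param profile Optional W x 4 profile; default [default_profile()].
#' @param motif Planted dinucleotide, two bases over \{A,C,G,U\}.
#' @return List of `n_pos + n_neg` labelled `rna_window`s.
#' @export
synth_windows <- function(n_pos, n_neg, W = 41L, effect = 1, seed = 1L,
                          profile = NULL, motif = "AG") {
  if (effect < 0) stop("effect must be nonnegative")
  if (nchar(motif) != 2L) stop("motif must be a dinucleotide")
  if (is.null(profile)) profile <- default_profile(W)
  stopifnot(nrow(profile) == W, ncol(profile) == 4L)
  if (any(abs(rowSums(profile) - 1) > 1e-9))
    stop("profile rows must sum to 1")
  center <- (W + 1L) / 2L
  if (profile[center, 1L] != 1)
    stop("profile centre row must force A")
  set.seed(seed)
  motif_bases <- strsplit(normalize_rna(motif), "")[[1L]]
  anchors <- signal_anchors(W)
  p_plant <- 1 - exp(-effect / 2)
  draw <- function(i, positive) {
    bases <- vapply(seq_len(W), function(pos) {
      sample(RNA_BASES, 1L, prob = profile[pos, ])
    }, character(1L))
    if (positive && p_plant > 0) {
      plant <- anchors[stats::runif(length(anchors)) < p_plant]
      for (a in plant) bases[a:(a + 1L)] <- motif_bases
      bases[center] <- "A"
    }
    rna_window(paste(bases, collapse = ""),
               id = sprintf("%s%04d", if (positive) "pos" else "neg", i),
               label = if (positive) "positive" else "negative")
  }
  c(lapply(seq_len(n_pos), draw, positive = TRUE),
    lapply(seq_len(n_neg), draw, positive = FALSE))
}

#' Write windows to FASTA with labels in the headers
#'
#' Headers take the form `id|label=pos` / `id|label=neg` (or
#' `id|label=na` for unlabeled windows) and round-trip through
#' [read_fasta()] / [parse_labeled_fasta()].
#'
#' @param windows List of `rna_window`s.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(windows, path) {
  if (length(windows) == 0L) {
    warning("writing empty FASTA file")
    file.create(path)
    return(invisible(path))
  }
  seqs <- vapply(windows, function(w) w$seq, character(1L))
  tag <- c(positive = "pos", negative = "neg", unlabeled = "na")
  hdr <- vapply(windows, function(w) {
    sprintf("%s|label=%s", w$id, tag[[w$label]])
  }, character(1L))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a labelled FASTA back into validated windows
#'
#' @param path FASTA path with `|label=pos|neg` headers as written by
#'   [write_fasta()].
#' @param W Odd window length for validation.
#' @return List of `rna_window`s; records failing window validation are
#'   skipped with a warning naming the count.
#' @export
parse_labeled_fasta <- function(path, W = 41L) {
  rec <- read_fasta(path)
  lab <- rep("unlabeled", nrow(rec))
  lab[grepl("\\|label=pos", rec$id)] <- "positive"
  lab[grepl("\\|label=neg", rec$id)] <- "negative"
  ids <- sub("\\|label=.*$", "", rec$id)
  out <- vector("list", nrow(rec))
  bad <- 0L
  for (i in seq_len(nrow(rec))) {
    w <- tryCatch(validate_window(rec$seq[i], W = W, id = ids[i],
                                  label = lab[i]),
                  error = function(e) NULL)
    if (is.null(w)) bad <- bad + 1L else out[[i]] <- w
  }
  if (bad > 0L)
    warning(bad, " record(s) failed window validation and were skipped")
  Filter(Negate(is.null), out)
}
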