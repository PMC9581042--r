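# Evolutionary node features: PSSM and self-entropy from an MSA.

# Profile alphabet: 20 amino acids + gap. One-hot alphabet: 20 + X.
PROFILE_ALPHABET <- c(AA20, "-")
ONEHOT_ALPHABET <- c(AA20, "X")

# BLOSUM62 amino-acid background frequencies (Henikoff & Henikoff counts).
BLOSUM62_BG <- c(
  A = 0.074, C = 0.025, D = 0.054, E = 0.054, F = 0.047, G = 0.074,
  H = 0.026, I = 0.068, K = 0.058, L = 0.099, M = 0.025, N = 0.045,
  P = 0.039, Q = 0.034, R = 0.052, S = 0.057, T = 0.051, V = 0.073,
  W = 0.013, Y = 0.032
)

#' Background frequencies over the 21-letter profile alphabet
#'
#' BLOSUM62 amino-acid backgrounds renormalized to `1 - gap_weight`, plus a
#' gap background of `gap_weight`.
#'
#' @param gap_weight Background probability assigned to the gap symbol.
#' @return Named numeric vector over the 20 amino acids and `"-"`, summing
#'   to 1.
#' @export
ipr_background <- function(gap_weight = 0.05) {
  if (gap_weight < 0 || gap_weight >= 1) stopf("gap_weight must be in [0, 1)")
  aa <- BLOSUM62_BG[AA20] / sum(BLOSUM62_BG) * (1 - gap_weight)
  c(aa, "-" = gap_weight)
}

#' Read a multiple sequence alignment (FASTA or A3M)
#'
#' The first row is the query. A3M lowercase insert states (and `.`
#' placeholders) are removed so all rows live in query-column space; rows
#' are upper-cased and letters outside the 20 amino acids map to `X`
#' (gaps stay `-`).
#'
#' @param path Alignment file.
#' @param format `"auto"` (by extension), `"fasta"` or `"a3m"`.
#' @return An object of class `ipr_msa`: list with `query` (ungapped query
#'   string), `rows` (aligned sequences), `names`.
#' @export
ipr_read_msa <- function(path, format = c("auto", "fasta", "a3m")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m" else "fasta"
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("empty alignment file: %s", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stopf("%s: expected FASTA-style '>' headers", path)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1L), collapse = "")
  nms <- sub("^>", "", lines[hdr])
  if (format == "a3m") seqs <- gsub("[a-z.]", "", seqs)
  seqs <- toupper(seqs)
  seqs <- vapply(seqs, function(s) {
    chartr_src <- setdiff(unique(strsplit(s, "")[[1L]]), c(AA20, "-"))
    for (ch in chartr_src) s <- gsub(ch, "X", s, fixed = TRUE)
    s
  }, character(1L), USE.NAMES = FALSE)
  len <- nchar(seqs)
  if (length(unique(len)) != 1L)
    stopf("%s: ragged alignment after normalization (lengths %s)",
          path, paste(sort(unique(len)), collapse = ", "))
  structure(list(query = gsub("-", "", seqs[1L]), rows = unname(seqs),
                 names = nms),
            class = "ipr_msa")
}

#' Build an MSA object from in-memory sequences
#'
#' @param rows Character vector of equal-length aligned sequences; first row
#'   is the query.
#' @param names Optional sequence names.
#' @return An `ipr_msa` object.
#' @export
ipr_msa <- function(rows, names = paste0("seq", seq_along(rows))) {
  if (length(rows) < 1L) stopf("MSA needs at least one row")
  if (length(unique(nchar(rows))) != 1L) stopf("MSA rows must have equal length")
  structure(list(query = gsub("-", "", toupper(rows[1L])),
                 rows = toupper(rows), names = names),
            class = "ipr_msa")
}

#' @export
print.ipr_msa <- function(x, ...) {
  cat(sprintf("<ipr_msa> %d rows x %d columns (query %d residues)\n",
              length(x$rows), nchar(x$rows[1L]), nchar(x$query)))
  invisible(x)
}

#' Per-column residue frequencies of an MSA
#'
#' Counts the 20 amino acids and the gap symbol per column (`X` and other
#' unknowns are ignored) and mixes in `pseudocount` total weight of the
#' background so every frequency is strictly positive:
#' `p = (count + pseudocount * background) / (n_observed + pseudocount)`.
#'
#' @param msa An `ipr_msa`.
#' @param pseudocount Total pseudocount weight (0 disables it).
#' @param background Background vector from [ipr_background()].
#' @return Matrix (columns x 21) of frequencies; rows sum to 1.
#' @export
ipr_column_frequencies <- function(msa, pseudocount = 1,
                                   background = ipr_background()) {
  chars <- do.call(rbind, strsplit(msa$rows, ""))
  L <- ncol(chars)
  counts <- vapply(PROFILE_ALPHABET, function(a) colSums(chars == a),
                   numeric(L))
  if (L == 1L) counts <- matrix(counts, nrow = 1L,
                                dimnames = list(NULL, PROFILE_ALPHABET))
  n_obs <- rowSums(counts)
  if (any(n_obs == 0L) && pseudocount <= 0)
    stopf("column with no countable symbols and no pseudocount")
  p <- sweep(counts + pseudocount * matrix(background, L, 21L, byrow = TRUE),
             1L, n_obs + pseudocount, `/`)
  colnames(p) <- PROFILE_ALPHABET
  p
}

#' Position-specific scoring matrix
#'
#' `PSSM = -log(p / p_b)` per position and symbol: negative where a symbol
#' is enriched over background, zero where observed equals background.
#'
#' @param p Frequency matrix from [ipr_column_frequencies()]
#'   (positions x 21).
#' @param background Background frequencies.
#' @param base `"natural"` or `"log2"`.
#' @return Matrix of the same shape as `p`.
#' @export
ipr_pssm <- function(p, background = ipr_background(),
                     base = c("natural", "log2")) {
  base <- match.arg(base)
  if (any(p <= 0) || any(background <= 0))
    stopf("ipr_pssm: frequencies must be strictly positive (use a pseudocount)")
  r <- -log(sweep(p, 2L, background, `/`))
  if (base == "log2") r <- r / log(2)
  r
}

#' Self-entropy
#'
#' `S = -p * log(p / p_b)` per position and symbol: the frequency-weighted
#' counterpart of the PSSM, satisfying `S = p * PSSM` elementwise.
#'
#' @inheritParams ipr_pssm
#' @return Matrix of the same shape as `p`.
#' @export
ipr_self_entropy <- function(p, background = ipr_background(),
                             base = c("natural", "log2")) {
  p * ipr_pssm(p, background, base)
}

#' Profile features for a receptor sequence
#'
#' Convenience wrapper computing frequencies, PSSM and self-entropy from an
#' MSA in one call.
#'
#' @inheritParams ipr_column_frequencies
#' @param base Logarithm base, see [ipr_pssm()].
#' @return An object of class `ipr_profile`: list with `pssm`,
#'   `self_entropy`, `p` (each positions x 21), `background`, `query`.
#' @export
ipr_profile <- function(msa, pseudocount = 1, background = ipr_background(),
                        base = c("natural", "log2")) {
  base <- match.arg(base)
  p <- ipr_column_frequencies(msa, pseudocount, background)
  structure(list(pssm = ipr_pssm(p, background, base),
                 self_entropy = ipr_self_entropy(p, background, base),
                 p = p, background = background, query = msa$query),
            class = "ipr_profile")
}

#' One-hot amino-acid encoding
#'
#' 21 slots: the 20 standard amino acids plus a dedicated slot for unknown
#' residues (`X`).
#'
#' @param aa1 Character vector of one-letter codes.
#' @return Matrix (length(aa1) x 21) with exactly one 1 per row.
#' @export
ipr_one_hot <- function(aa1) {
  idx <- match(aa1, ONEHOT_ALPHABET)
  if (anyNA(idx))
    stopf("unknown amino-acid letter(s): %s",
          paste(unique(aa1[is.na(idx)]), collapse = ", "))
  m <- matrix(0, length(aa1), 21L, dimnames = list(NULL, ONEHOT_ALPHABET))
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Write / read profile features as TSV
#'
#' 42 numeric columns per position: 21 PSSM values then 21 self-entropy
#' values, in profile-alphabet order (20 amino acids, then gap).
#'
#' @param profile An `ipr_profile`.
#' @param path Output file.
#' @return `path` (write) or an `ipr_profile` without frequencies (read).
#' @export
ipr_write_profile <- function(profile, path) {
  df <- data.frame(position = seq_len(nrow(profile$pssm)))
  pm <- profile$pssm; colnames(pm) <- paste0("pssm_", c(AA20, "gap"))
  sm <- profile$self_entropy; colnames(sm) <- paste0("entropy_", c(AA20, "gap"))
  write_tsv(cbind(df, pm, sm), path)
}

#' @rdname ipr_write_profile
#' @export
ipr_read_profile <- function(path) {
  df <- read_tsv(path)
  pssm <- as.matrix(df[, grep("^pssm_", names(df))])
  ent <- as.matrix(df[, grep("^entropy_", names(df))])
  colnames(pssm) <- colnames(ent) <- PROFILE_ALPHABET
  structure(list(pssm = pssm, self_entropy = ent, p = NULL,
                 background = NULL, query = NULL),
            class = "ipr_profile")
}
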