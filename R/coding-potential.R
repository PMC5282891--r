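# Three coding-potential filters and their consensus. Scores come in as a
# table (CPC-style, PLEK-style, minimum protein-domain E-value); the
# classifiers themselves are upstream producers, not reimplemented here.

.score_lookup <- function(scores, ids, col) {
  i <- match(ids, scores$transcript_id)
  if (anyNA(i))
    stop("missing coding scores for: ",
         paste(head(ids[is.na(i)], 5L), collapse = ", "))
  setNames(scores[[col]][i], ids)
}

#' Call noncoding transcripts from CPC-style scores
#'
#' A transcript is called noncoding iff its score is strictly below the
#' cutoff (default -0.5). The boundary value itself stays on the coding
#' side.
#'
#' @param scores coding score table (see [coding_scores()]).
#' @param ids transcript ids to evaluate (default: all scored).
#' @param cutoff score cutoff.
#' @return character vector of noncoding transcript ids.
#' @export
call_noncoding_cpc <- function(scores, ids = scores$transcript_id,
                               cutoff = -0.5) {
  s <- .score_lookup(scores, ids, "cpc_score")
  names(s)[s < cutoff]
}

#' Call noncoding transcripts from PLEK-style scores
#'
#' @inheritParams call_noncoding_cpc
#' @return character vector of noncoding transcript ids.
#' @export
call_noncoding_plek <- function(scores, ids = scores$transcript_id,
                                cutoff = -0.5) {
  s <- .score_lookup(scores, ids, "plek_score")
  names(s)[s < cutoff]
}

#' Call transcripts free of protein-domain hits
#'
#' A transcript is excluded iff its minimum domain E-value is strictly below
#' the threshold (default 1e-4, a confident domain hit); transcripts with no
#' hit (missing E-value) or weaker hits are retained.
#'
#' @param scores coding score table.
#' @param ids transcript ids to evaluate (default: all scored).
#' @param evalue_threshold E-value below which a domain hit disqualifies.
#' @return character vector of domain-free transcript ids.
#' @export
call_domain_free <- function(scores, ids = scores$transcript_id,
                             evalue_threshold = 1e-4) {
  ev <- .score_lookup(scores, ids, "min_domain_evalue")
  if (any(!is.na(ev) & ev < 0)) stop("negative domain E-value")
  names(ev)[is.na(ev) | ev >= evalue_threshold]
}

#' Consensus of the three coding-potential filters
#'
#' The putative lncRNA set is the exact three-way intersection of the
#' CPC-noncoding, PLEK-noncoding and domain-free sets.
#'
#' @param set_cpc,set_plek,set_domainfree character vectors of ids.
#' @return sorted character vector of consensus ids.
#' @export
consensus_lncrnas <- function(set_cpc, set_plek, set_domainfree) {
  sort(intersect(intersect(set_cpc, set_plek), set_domainfree))
}

#' Naive open-reading-frame coverage score
#'
#' Built-in fallback scorer so the pipeline can run without external
#' classifier output: `2 * (longest complete ORF length / sequence length)
#' - 1`, with ORFs (ATG to the first in-frame stop, inclusive) scanned in
#' the three forward frames. Returns -1 when no complete ORF exists and
#' approaches +1 as the longest ORF covers the whole sequence. Negative
#' values lean noncoding, so the score slots into the same cutoff logic as
#' the external classifiers.
#'
#' @param sequence character string over `A`, `C`, `G`, `T`, `N`.
#' @return score in `[-1, 1]`.
#' @export
naive_orf_score <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  if (n < 3L) stop("sequence shorter than one codon")
  if (grepl("[^ACGTN]", sequence)) stop("sequence has non-ACGTN symbols")
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    codons <- substring(sequence, starts, starts + 2L)
    open_at <- NA_integer_
    for (i in seq_along(codons)) {
      if (is.na(open_at) && codons[i] == "ATG") open_at <- i
      if (!is.na(open_at) && codons[i] %in% stops) {
        best <- max(best, (i - open_at + 1L) * 3L)
        open_at <- NA_integer_
      }
    }
  }
  if (best == 0L) return(-1)
  2 * best / n - 1
}
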