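#' Sample-specific protein-database reduction from 16S amplicons
#'
#' Participant 16S sequences are merged and deduplicated, locally aligned to
#' the reference 16S set, filtered to the most homologous hits (raw alignment
#' score strictly above `min_score`, then the per-query `top_k` by score), and
#' the proteins of every retained reference's taxon form the reduced
#' search database.
#'
#' @name db_reduction
NULL

#' Alignment and filtering parameters
#'
#' The score threshold is a raw local-alignment score and is only meaningful
#' for a concrete scoring scheme; the defaults are the classic nucleotide
#' BLAST rewards/penalties (match +2, mismatch -3, gap open 5, gap extend 2),
#' under which a perfect 250-nt V4 match scores 500 and the default
#' `min_score = 450` admits only near-full-length, high-identity hits.
#'
#' @param min_score retain hits with score strictly greater than this.
#' @param top_k per-query cap on retained hits.
#' @param match,mismatch,gap_open,gap_extend scoring scheme (costs positive).
#' @return a `reduction_params` list.
#' @export
reduction_params <- function(min_score = 450, top_k = 200, match = 2,
                             mismatch = -3, gap_open = 5, gap_extend = 2) {
  if (top_k < 1) stop("top_k must be >= 1")
  if (min_score < 0) stop("min_score must be >= 0")
  structure(list(min_score = min_score, top_k = top_k, match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "reduction_params")
}

as_named_seqs <- function(x, what) {
  if (inherits(x, "DNAStringSet")) {
    stats::setNames(as.character(x), names(x))
  } else if (is.character(x) && !is.null(names(x))) {
    toupper(x)
  } else {
    stop(what, " must be a named character vector or DNAStringSet")
  }
}

#' Merge FASTA inputs and drop exact duplicate sequences
#'
#' Sequences are case-normalised and deduplicated by exact string equality
#' (no clustering); order is stable by first occurrence.
#'
#' @param inputs character vector of FASTA paths, or a list of named
#'   character vectors / `DNAStringSet`s.
#' @return named character vector of unique sequences.
#' @export
merge_dedupe <- function(inputs) {
  if (length(inputs) == 0) return(stats::setNames(character(), character()))
  seq_sets <- lapply(inputs, function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      set <- tryCatch(Biostrings::readDNAStringSet(x),
                      error = function(e) stop("malformed FASTA ", x, ": ",
                                               conditionMessage(e)))
      stats::setNames(toupper(as.character(set)), names(set))
    } else {
      as_named_seqs(x, "input")
    }
  })
  all_seqs <- unlist(unname(seq_sets))
  all_seqs[!duplicated(unname(all_seqs))]
}

#' Local alignment of query 16S sequences against references
#'
#' Optimal Smith-Waterman local-alignment score under the affine-gap scheme in
#' `params`, computed with [Biostrings::pairwiseAlignment()] over a custom
#' substitution matrix in which `N` scores as a mismatch against every base
#' (including itself). One hit per (query, reference) pair with score > 0.
#'
#' @param queries,references named character vectors or `DNAStringSet`s over
#'   the alphabet A/C/G/T/N.
#' @param params a [reduction_params()].
#' @return data.frame: query_id, subject_id, score.
#' @export
align_16s <- function(queries, references, params = reduction_params()) {
  q <- as_named_seqs(queries, "queries")
  r <- as_named_seqs(references, "references")
  bad <- grepl("[^ACGTN]", c(q, r))
  if (any(bad)) {
    stop("non-nucleotide characters (other than N) in: ",
         paste(names(c(q, r))[bad], collapse = ", "))
  }
  bases <- c("A", "C", "G", "T", "N")
  mat <- matrix(params$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(mat)[1:4] <- params$match   # N-N stays a mismatch
  qset <- Biostrings::DNAStringSet(q)
  out <- vector("list", length(r))
  for (j in seq_along(r)) {
    sc <- Biostrings::pairwiseAlignment(
      pattern = qset, subject = r[[j]], type = "local",
      substitutionMatrix = mat, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, scoreOnly = TRUE)
    out[[j]] <- data.frame(query_id = names(q), subject_id = names(r)[j],
                           score = sc, stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  hits <- hits[hits$score > 0, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Filter alignment hits to the most homologous per query
#'
#' Per query: keep hits with score strictly greater than `min_score`, then the
#' `top_k` by descending score; ties at the cutoff break by subject_id
#' lexicographic order (strict top-k, tied hits beyond k are dropped).
#'
#' @param hits a data.frame from [align_16s()].
#' @param params a [reduction_params()].
#' @return `hits` with a logical `retained` column added.
#' @export
filter_hits <- function(hits, params = reduction_params()) {
  hits$retained <- FALSE
  for (qid in unique(hits$query_id)) {
    idx <- which(hits$query_id == qid & hits$score > params$min_score)
    if (!length(idx)) next
    ord <- idx[order(-hits$score[idx], hits$subject_id[idx])]
    hits$retained[ord[seq_len(min(params$top_k, length(ord)))]] <- TRUE
  }
  hits
}

#' Build the reduced protein database from retained hits
#'
#' The union, over all retained reference subjects, of every protein of the
#' subject's taxon; each protein is emitted once, with a provenance row
#' recording its taxon and the number of distinct supporting queries.
#'
#' @param hits a [filter_hits()] result (uses rows with `retained = TRUE`).
#' @param bundle a [make_reference_bundle()]-shaped bundle (`ref16s`,
#'   `proteins`).
#' @return list: `proteins` (protein_id, taxon_id, sequence) and `provenance`
#'   (protein_id, taxon_id, n_queries).
#' @export
build_reduced_db <- function(hits, bundle) {
  if (is.null(hits$retained)) stop("hits must be filtered first (no 'retained' column)")
  ret <- hits[hits$retained, , drop = FALSE]
  offenders <- setdiff(unique(ret$subject_id), bundle$ref16s$seq_id)
  if (length(offenders)) {
    stop("retained subject(s) without taxon mapping: ",
         paste(offenders, collapse = ", "))
  }
  subj_tax <- stats::setNames(bundle$ref16s$taxon_id, bundle$ref16s$seq_id)
  ret$taxon_id <- unname(subj_tax[ret$subject_id])
  taxa <- unique(ret$taxon_id)
  prot <- bundle$proteins[bundle$proteins$taxon_id %in% taxa, , drop = FALSE]
  prot <- prot[!duplicated(prot$protein_id), , drop = FALSE]
  nq <- vapply(split(ret$query_id, ret$taxon_id),
               function(v) length(unique(v)), integer(1))
  provenance <- data.frame(protein_id = prot$protein_id,
                           taxon_id = prot$taxon_id,
                           n_queries = unname(nq[prot$taxon_id]),
                           stringsAsFactors = FALSE)
  rownames(prot) <- rownames(provenance) <- NULL
  list(proteins = prot, provenance = provenance)
}

#' Ingest external tabular alignment output (outfmt-6-like TSV)
#'
#' Adapter for users who prefer an external aligner: reads a headerless
#' 12-column tab-separated hit table and returns the three columns
#' [filter_hits()] needs (the raw score is taken from column 12).
#'
#' @param path TSV path.
#' @return data.frame: query_id, subject_id, score.
#' @export
read_tabular_hits <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected >= 12 tab-separated columns")
  data.frame(query_id = as.character(df[[1]]),
             subject_id = as.character(df[[2]]),
             score = as.numeric(df[[12]]), stringsAsFactors = FALSE)
}
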