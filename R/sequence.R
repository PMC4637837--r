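#' Protein sequence entry
#'
#' @param accession Sequence-database identifier.
#' @param sequence Amino-acid string (20 standard letters plus `X`).
#' @param organism Optional organism label.
#' @return An object of class `protein_entry`.
#' @export
protein_entry <- function(accession, sequence, organism = NA_character_) {
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)) {
    stop("sequence contains letters outside the 20 amino acids + X")
  }
  structure(list(accession = as.character(accession), sequence = sequence,
                 organism = organism),
            class = "protein_entry")
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named list of [protein_entry()] keyed by accession (the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta_proteins <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  accs <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  out <- lapply(seq_along(ss), function(i)
    protein_entry(accs[i], as.character(ss[[i]])))
  setNames(out, accs)
}

#' Binary interaction record
#'
#' An undirected protein pair from an interaction table; `(A,B)` and
#' `(B,A)` denote the same interaction.  Self-interactions (`acc_a ==
#' acc_b`) are retained, since homodimer templates are legitimate building
#' blocks.
#'
#' @param acc_a,acc_b Interactor accessions (non-empty).
#' @param detection_method Free-text experimental method label.
#' @param source_id Record identifier in the source database.
#' @return An object of class `interaction_record`.
#' @export
interaction_record <- function(acc_a, acc_b, detection_method = "",
                               source_id = "") {
  if (!nzchar(acc_a) || !nzchar(acc_b)) stop("accessions must be non-empty")
  structure(list(acc_a = as.character(acc_a), acc_b = as.character(acc_b),
                 detection_method = as.character(detection_method),
                 source_id = as.character(source_id)),
            class = "interaction_record")
}

#' Canonical (sorted) key of an interaction pair
#' @param rec An `interaction_record`, or a character 2-vector.
#' @return Character scalar `"A|B"` with accessions sorted.
#' @export
pair_key <- function(rec) {
  p <- if (inherits(rec, "interaction_record")) c(rec$acc_a, rec$acc_b)
       else as.character(rec)
  paste(sort(p), collapse = "|")
}

#' Read a MITAB-style binary interaction table
#'
#' Expects a TSV with columns `acc_a`, `acc_b`, `detection_method`,
#' `source_id` (header required).  Duplicate unordered pairs are kept; they
#' are distinct experimental observations.
#'
#' @param path TSV path.
#' @return List of [interaction_record()].
#' @export
read_interactions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("acc_a", "acc_b") %in% names(tab)))
  if (is.null(tab$detection_method)) tab$detection_method <- ""
  if (is.null(tab$source_id)) tab$source_id <- ""
  lapply(seq_len(nrow(tab)), function(i)
    interaction_record(tab$acc_a[i], tab$acc_b[i], tab$detection_method[i],
                       tab$source_id[i]))
}

#' Local pairwise sequence alignment with identity
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1).
#' Identity is computed over the aligned (gap-free) columns only; columns
#' where either side is gapped do not enter the denominator.  Alignments
#' scoring below `min_score` are treated as no alignment: random short
#' sequences otherwise always produce some tiny positive-scoring local hit,
#' which would make any identity threshold meaningless.
#'
#' @param query,subject [protein_entry()] objects (or amino-acid strings).
#' @param min_score Score floor below which the alignment is discarded
#'   (default 25, roughly the shortest run of identities that is unlikely by
#'   chance between unrelated sequences).
#' @return List of class `alignment_result` with `identity_fraction` (in
#'   `[0,1]`), `aligned_pairs` (two-column matrix of 1-based query/subject
#'   indices, strictly increasing in both), and `score`.
#' @export
align_pair <- function(query, subject, min_score = 25) {
  qs <- if (inherits(query, "protein_entry")) query$sequence else
    toupper(as.character(query))
  ss <- if (inherits(subject, "protein_entry")) subject$sequence else
    toupper(as.character(subject))
  if (!nzchar(qs) || !nzchar(ss)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    qs, ss, type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  sc <- Biostrings::score(aln)
  empty <- structure(list(identity_fraction = 0,
                          aligned_pairs = matrix(integer(), ncol = 2,
                            dimnames = list(NULL, c("query", "subject"))),
                          score = sc),
                     class = "alignment_result")
  if (sc < min_score) return(empty)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qi <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  si <- Biostrings::start(Biostrings::subject(aln)) - 1L
  pairs <- matrix(integer(), ncol = 2)
  n_id <- 0L; n_cols <- 0L
  qpos <- integer(length(pat)); spos <- integer(length(pat))
  k <- 0L
  for (j in seq_along(pat)) {
    if (pat[j] != "-") qi <- qi + 1L
    if (sub[j] != "-") si <- si + 1L
    if (pat[j] != "-" && sub[j] != "-") {
      k <- k + 1L
      qpos[k] <- qi; spos[k] <- si
      n_cols <- n_cols + 1L
      if (pat[j] == sub[j]) n_id <- n_id + 1L
    }
  }
  if (k == 0L) return(empty)
  structure(list(identity_fraction = n_id / n_cols,
                 aligned_pairs = cbind(query = qpos[seq_len(k)],
                                       subject = spos[seq_len(k)]),
                 score = sc),
            class = "alignment_result")
}

# sequence of a library member: accepts chain_structure or protein_entry
.seq_of <- function(x) {
  if (inherits(x, "chain_structure")) chain_sequence(x)
  else if (inherits(x, "protein_entry")) x$sequence
  else as.character(x)
}

#' Find homologous chains in a structure library
#'
#' Library chains aligning to the query with identity strictly greater than
#' `min_identity` are returned sorted by identity (descending).  Coverage is
#' deliberately not a filter: partially determined template structures are
#' admitted, and quality control happens later at the superposition gate.
#'
#' @param query A [protein_entry()].
#' @param library List of [chain_structure()] (sequences taken from their
#'   residue tables).
#' @param min_identity Exclusive identity threshold, default 0.25.
#' @return List of `list(chain=, alignment=)`, identity descending; ties
#'   broken by (source_entry, chain_id).
#' @export
find_homologues <- function(query, library, min_identity = 0.25) {
  stopifnot(min_identity >= 0, min_identity <= 1)
  hits <- list()
  for (ch in library) {
    aln <- align_pair(query, .seq_of(ch))
    if (aln$identity_fraction > min_identity) {
      hits[[length(hits) + 1L]] <- list(chain = ch, alignment = aln)
    }
  }
  if (length(hits) == 0) return(hits)
  idf <- vapply(hits, function(h) h$alignment$identity_fraction, numeric(1))
  ent <- vapply(hits, function(h) h$chain$source_entry, character(1))
  cid <- vapply(hits, function(h) h$chain$chain_id, character(1))
  hits[order(-idf, ent, cid)]
}

#' Classify an interaction against the structure library
#'
#' Four-way classification of a recorded binary interaction:
#' * `complex` — some single structure entry contains homologues of both
#'   partners as co-determined chains (a usable binary template exists);
#' * `independent` — both partners have homologous structures, but never in
#'   the same entry;
#' * `one_sided` — exactly one partner has a homologue;
#' * `unknown` — neither does.
#'
#' @param rec An [interaction_record()].
#' @param proteins Named list of [protein_entry()] keyed by accession.
#' @param library List of [chain_structure()].
#' @param min_identity Exclusive identity threshold, default 0.25.
#' @return Character scalar, one of the four category labels.
#' @export
classify_interaction <- function(rec, proteins, library, min_identity = 0.25) {
  for (acc in unique(c(rec$acc_a, rec$acc_b))) {
    if (is.null(proteins[[acc]])) stop("no sequence for accession ", acc)
  }
  ha <- find_homologues(proteins[[rec$acc_a]], library, min_identity)
  hb <- find_homologues(proteins[[rec$acc_b]], library, min_identity)
  if (length(ha) == 0 && length(hb) == 0) return("unknown")
  if (length(ha) == 0 || length(hb) == 0) return("one_sided")
  ent_a <- vapply(ha, function(h) h$chain$source_entry, character(1))
  ent_b <- vapply(hb, function(h) h$chain$source_entry, character(1))
  shared <- intersect(ent_a, ent_b)
  if (rec$acc_a == rec$acc_b) {
    # homodimer: need two distinct homologous chains in one entry
    for (e in unique(ent_a)) {
      ids <- unique(vapply(ha[ent_a == e], function(h) h$chain$chain_id,
                           character(1)))
      if (length(ids) >= 2) return("complex")
    }
    return("independent")
  }
  for (e in shared) {
    ids_a <- unique(vapply(ha[ent_a == e], function(h) h$chain$chain_id,
                           character(1)))
    ids_b <- unique(vapply(hb[ent_b == e], function(h) h$chain$chain_id,
                           character(1)))
    # co-determined: a chain for A and a different chain for B in one entry
    if (length(unique(c(ids_a, ids_b))) >= 2) return("complex")
  }
  "independent"
}
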