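# Dataset curation: the filters used to assemble a non-redundant set of
# protein-RNA complexes from a candidate list (resolution, chain lengths,
# modified-base content, ribosome exclusion, sequence redundancy).

#' Global protein sequence identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
#' gap penalty -1 (via Biostrings), with identity defined as the number of
#' identical aligned positions divided by the length of the shorter
#' sequence.
#'
#' @param a,b protein sequences as one-letter-code strings.
#' @return identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  alphabet <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  sub_mat <- matrix(0, length(alphabet), length(alphabet),
                    dimnames = list(alphabet, alphabet))
  diag(sub_mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    type = "global", substitutionMatrix = sub_mat,
    gapOpening = 0, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(p == s & p != "-")
  matches / min(nchar(a), nchar(b))
}

#' Group redundant entries
#'
#' Entries whose protein sequence identity exceeds 0.9 *and* whose RNA
#' sequences are identical are placed in one redundancy group (transitive
#' closure); one representative is kept per group: best resolution first,
#' X-ray entries ranked before NMR, ties broken by lexicographic id.
#'
#' @param entries data.frame with columns `id`, `method`, `resolution`,
#'   `protein_seq`, `rna_seq`.
#' @param identity_threshold redundancy threshold (strictly greater than;
#'   default 0.9).
#' @return list with `group` (integer vector parallel to `entries`) and
#'   `representative` (logical vector, `TRUE` for the kept entry).
#' @export
deduplicate <- function(entries, identity_threshold = 0.9) {
  n <- nrow(entries)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (!identical(entries$rna_seq[i], entries$rna_seq[j])) next
        idty <- sequence_identity(entries$protein_seq[i],
                                  entries$protein_seq[j])
        if (idty > identity_threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  group <- vapply(seq_len(n), find, integer(1))
  group <- match(group, unique(group))
  representative <- logical(n)
  for (g in unique(group)) {
    members <- which(group == g)
    method_rank <- ifelse(tolower(entries$method[members]) == "xray", 0, 1)
    res <- entries$resolution[members]
    res[is.na(res)] <- Inf
    ord <- order(method_rank, res, entries$id[members])
    representative[members[ord[1]]] <- TRUE
  }
  list(group = group, representative = representative)
}

#' Apply the dataset-curation filters
#'
#' Filters, in order of precedence for the reported drop reason:
#' (1) X-ray entries with resolution above 3.0 A (or missing resolution
#' metadata) are dropped; (2) entries whose protein chains are all shorter
#' than 10 amino acids; (3) entries whose RNA is shorter than 10
#' nucleotides; (4) entries whose RNA carries more than 50 percent
#' modified nucleobases; (5) entries flagged as ribosomes via the
#' user-supplied keyword/id list; (6) redundant entries (protein identity
#' > 0.9 with identical RNA sequence), keeping one representative per
#' group. NMR entries are exempt from the resolution filter.
#'
#' @param entries data.frame with columns `id`, `method` (`"xray"`/
#'   `"nmr"`/other), `resolution` (Angstrom, `NA` allowed for non-X-ray),
#'   `protein_length` (longest protein chain, residues), `rna_length`
#'   (longest RNA chain, nucleotides), `modified_fraction` (\[0, 1\]), and
#'   for redundancy removal `protein_seq`, `rna_seq`. Optional `title`
#'   used for keyword matching.
#' @param ribosome_ids character vector of entry ids to drop as ribosomes.
#' @param ribosome_keywords keywords matched (case-insensitively) against
#'   `title`.
#' @return data.frame of class `curation_report`: the input columns plus
#'   `redundancy_group`, `decision` (`"keep"`/`"drop"`) and `reason`
#'   (one primary reason per drop: `resolution`, `metadata`,
#'   `protein_length`, `rna_length`, `modified_bases`, `ribosome`,
#'   `redundant`).
#' @export
apply_filters <- function(entries, ribosome_ids = character(0),
                          ribosome_keywords = c("ribosome", "ribosomal subunit")) {
  need <- c("id", "method", "resolution", "protein_length", "rna_length",
            "modified_fraction")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(entries)
  reason <- rep(NA_character_, n)

  is_xray <- tolower(entries$method) == "xray"
  bad_meta <- is_xray & is.na(entries$resolution)
  bad_res <- is_xray & !is.na(entries$resolution) & entries$resolution > 3.0
  reason[bad_res & is.na(reason)] <- "resolution"
  reason[bad_meta & is.na(reason)] <- "metadata"
  reason[entries$protein_length < 10 & is.na(reason)] <- "protein_length"
  reason[entries$rna_length < 10 & is.na(reason)] <- "rna_length"
  reason[entries$modified_fraction > 0.5 & is.na(reason)] <- "modified_bases"

  is_ribo <- entries$id %in% ribosome_ids
  if (!is.null(entries$title) && length(ribosome_keywords) > 0) {
    pat <- paste(ribosome_keywords, collapse = "|")
    is_ribo <- is_ribo | grepl(pat, entries$title, ignore.case = TRUE)
  }
  reason[is_ribo & is.na(reason)] <- "ribosome"

  # redundancy among entries that survived filters 1-5
  entries$redundancy_group <- NA_integer_
  survivors <- which(is.na(reason))
  if (length(survivors) > 1 &&
      all(c("protein_seq", "rna_seq") %in% names(entries))) {
    dd <- deduplicate(entries[survivors, , drop = FALSE])
    entries$redundancy_group[survivors] <- dd$group
    reason[survivors[!dd$representative]] <- "redundant"
  }

  entries$decision <- ifelse(is.na(reason), "keep", "drop")
  entries$reason <- ifelse(is.na(reason), "", reason)
  class(entries) <- c("curation_report", class(entries))
  entries
}

#' Build a curation manifest from parsed structures
#'
#' Extracts the metadata consumed by [apply_filters()] from cleaned
#' structures: method, resolution, longest protein/RNA chain lengths,
#' modified-base fraction and one-letter sequences of the longest chains.
#'
#' @param structures list of cleaned `rnp_structure` objects.
#' @return data.frame manifest.
#' @export
curation_manifest <- function(structures) {
  rows <- lapply(structures, function(s) {
    res_tab <- residue_table(s)
    ent <- s$entities
    pl <- vapply(names(ent)[ent == "protein"], function(ch) {
      sum(res_tab$chain == ch & res_tab$kind == "amino_acid")
    }, integer(1))
    rl <- vapply(names(ent)[ent == "rna"], function(ch) {
      sum(res_tab$chain == ch & res_tab$kind == "nucleotide")
    }, integer(1))
    mf <- if (length(rl) > 0) modified_base_fraction(s)$overall else NA_real_
    pseq <- if (length(pl) > 0) {
      ch <- names(pl)[which.max(pl)]
      r <- res_tab[res_tab$chain == ch & res_tab$kind == "amino_acid", ]
      paste(ifelse(r$standard_parent %in% names(AA_3TO1),
                   AA_3TO1[r$standard_parent], "X"), collapse = "")
    } else ""
    rseq <- if (length(rl) > 0) {
      ch <- names(rl)[which.max(rl)]
      r <- res_tab[res_tab$chain == ch & res_tab$kind == "nucleotide", ]
      paste(ifelse(r$standard_parent == "", "N", r$standard_parent),
            collapse = "")
    } else ""
    data.frame(id = s$id, method = s$method, resolution = s$resolution,
               protein_length = if (length(pl)) max(pl) else 0L,
               rna_length = if (length(rl)) max(rl) else 0L,
               modified_fraction = mf, protein_seq = pseq, rna_seq = rseq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
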