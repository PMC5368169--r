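# RING zinc-finger domain screen: parse domain-annotation tables, locate the
# eight metal-ligand residues from the canonical spacing pattern, classify
# the RING subtype, and reconcile gene sets between genome releases.

#' Member databases accepted as RING signature evidence
#' @export
ring_signature_dbs <- function() {
  c("Gene3D", "SUPERFAMILY", "ProSiteProfiles", "SMART", "Pfam", "ProSitePatterns")
}

#' Parse an InterProScan-style domain annotation TSV
#'
#' Reads the standard tabular layout (protein accession, md5, length,
#' analysis, signature accession, signature description, start, stop, score,
#' status, date, ...). Malformed rows (too few columns, non-numeric or
#' inverted coordinates) are skipped with a message; annotations from member
#' databases outside the six RING signature sources are retained but
#' flagged.
#'
#' @param path TSV file path.
#' @return data.frame with columns `protein_id`, `signature_db`,
#'   `signature_accession`, `start`, `end`, `known_db`.
#' @export
parse_domain_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L) {
      message("parse_domain_table: skipping malformed line ", i, " (too few columns)")
      next
    }
    start <- suppressWarnings(as.integer(f[7L]))
    end <- suppressWarnings(as.integer(f[8L]))
    if (is.na(start) || is.na(end) || start < 1L || end < start) {
      message("parse_domain_table: skipping malformed line ", i, " (bad coordinates)")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = f[1L], signature_db = f[4L], signature_accession = f[5L],
      start = start, end = end, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), signature_db = character(0),
               signature_accession = character(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  out$known_db <- out$signature_db %in% ring_signature_dbs()
  out
}

#' Canonical RING metal-ligand spacing bounds
#'
#' The consensus spacing
#' `M1-x2-M2-x(9..39)-M3-x(1..3)-M4-x(2..3)-M5-x2-M6-x(4..48)-M7-x2-M8`,
#' where metal positions 1, 2, 3, 6, 7, 8 are cysteine and positions 4 and 5
#' may be any of C, H, D, S, T. The bounds are configuration, not constants:
#' pass a modified list to [locate_ring_ligands()] to match other published
#' scheme revisions.
#'
#' @return List with `gap_bounds` (7 x 2 matrix of inclusive gap ranges) and
#'   `residues` (per-position allowed residue sets).
#' @export
ring_spacing <- function() {
  list(
    gap_bounds = matrix(c(2, 2,  9, 39,  1, 3,  2, 3,  2, 2,  4, 48,  2, 2),
                        ncol = 2L, byrow = TRUE),
    residues = list("C", "C", "C", c("C", "H", "D", "S", "T"),
                    c("C", "H", "D", "S", "T"), "C", "C", "C")
  )
}

#' Locate the eight RING metal-ligand residues
#'
#' Searches a protein sequence (optionally restricted to an annotated span)
#' for the canonical RING spacing pattern. The leftmost-longest match wins:
#' the match starting earliest; among matches with that start, the one
#' ending latest; remaining interior ambiguity is resolved greedily from the
#' left (each gap as long as possible).
#'
#' @param sequence amino-acid sequence (single string).
#' @param span optional `c(start, end)` 1-based inclusive window.
#' @param spacing spacing configuration from [ring_spacing()].
#' @return List with `positions` (8 increasing 1-based indices) and
#'   `residues` (8 characters), or `NULL` when no canonical match exists.
#' @export
locate_ring_ligands <- function(sequence, span = NULL, spacing = ring_spacing()) {
  sequence <- toupper(as.character(sequence))
  n <- nchar(sequence)
  if (is.null(span)) span <- c(1L, n)
  if (span[1L] < 1L || span[2L] > n || span[1L] > span[2L]) {
    stop("span outside sequence")
  }
  sub <- substr(sequence, span[1L], span[2L])
  rx_full <- ring_regex(spacing, anchored = FALSE)
  m <- regexpr(rx_full, sub, perl = TRUE)
  if (m == -1L) return(NULL)
  start <- as.integer(m)
  # extend to the longest match at this start
  rx_anch <- ring_regex(spacing, anchored = TRUE)
  best <- NULL
  for (end in nchar(sub):start) {
    mm <- regexpr(rx_anch, substr(sub, start, end), perl = TRUE)
    if (mm != -1L) {
      cs <- attr(mm, "capture.start")
      best <- as.integer(cs) + start - 1L
      break
    }
  }
  if (is.null(best)) return(NULL)
  positions <- best + span[1L] - 1L
  list(positions = positions,
       residues = vapply(positions, function(p) substr(sequence, p, p), character(1)))
}

ring_regex <- function(spacing, anchored = FALSE) {
  res_class <- vapply(spacing$residues, function(r) {
    if (length(r) == 1L) r else paste0("[", paste(r, collapse = ""), "]")
  }, character(1))
  gb <- spacing$gap_bounds
  gaps <- vapply(seq_len(nrow(gb)), function(i) {
    if (gb[i, 1L] == gb[i, 2L]) sprintf(".{%d}", gb[i, 1L])
    else sprintf(".{%d,%d}", gb[i, 1L], gb[i, 2L])
  }, character(1))
  body <- paste0("(", res_class[1L], ")")
  for (i in 1:7) body <- paste0(body, gaps[i], "(", res_class[i + 1L], ")")
  if (anchored) paste0("^", body, "$") else body
}

#' Classify a RING subtype from its eight metal-ligand residues
#'
#' Applies the editable rule table shipped at
#' `system.file("extdata", "ring_classes.csv", package = "phenoscreen")` in
#' priority order: the His/Cys identity of metal positions 4 and 5
#' distinguishes HC, H2 and v (CH); all-cysteine domains are C2; an Asp,
#' Ser/Thr or Gly at any metal position gives the D, S/T or G subtype;
#' anything else is non-canonical. The function is total over arbitrary
#' residue 8-tuples.
#'
#' @param residues character vector of 8 single residues.
#' @param rules rule table (data.frame as in the shipped CSV).
#' @return A single class label.
#' @examples
#' classify_ring(c("C", "C", "C", "H", "C", "C", "C", "C"))  # "HC"
#' @export
classify_ring <- function(residues, rules = ring_class_rules()) {
  if (length(residues) != 8L) stop("classify_ring needs exactly 8 residues")
  residues <- toupper(residues)
  for (i in order(rules$priority)) {
    cond <- rules$condition[i]
    val <- strsplit(rules$value[i], ":", fixed = TRUE)[[1L]]
    hit <- switch(cond,
      pair45 = residues[4L] == val[1L] && residues[5L] == val[2L],
      all_cys = all(residues == "C"),
      any = any(residues %in% val),
      default = TRUE,
      stop("unknown rule condition: ", cond)
    )
    if (hit) return(rules$class[i])
  }
  "non-canonical"
}

ring_class_rules <- function() {
  path <- system.file("extdata", "ring_classes.csv", package = "phenoscreen")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Screen a proteome for canonical RING domains
#'
#' For every annotated span from one of the six RING signature databases,
#' attempts to locate the eight metal ligands and classify the subtype.
#' Proteins with signature evidence but no successful ligand location are
#' reported in a separate `signature_only` tier rather than silently
#' dropped.
#'
#' @param proteins named character vector of sequences or a
#'   `Biostrings::AAStringSet`.
#' @param annotations data.frame from [parse_domain_table()].
#' @param spacing spacing configuration, see [ring_spacing()].
#' @return List with `hits` (data.frame: protein_id, span, 8 ligand
#'   positions and residues, ring_class) and `signature_only` (character
#'   vector of protein ids).
#' @export
find_ring_domains <- function(proteins, annotations, spacing = ring_spacing()) {
  if (methods::is(proteins, "AAStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  ann <- annotations[annotations$known_db %in% TRUE |
                       annotations$signature_db %in% ring_signature_dbs(), ,
                     drop = FALSE]
  hits <- list()
  attempted <- character(0)
  located <- character(0)
  for (i in seq_len(nrow(ann))) {
    pid <- ann$protein_id[i]
    if (!pid %in% names(proteins)) next
    attempted <- c(attempted, pid)
    seqc <- proteins[[pid]]
    span <- c(ann$start[i], min(ann$end[i], nchar(seqc)))
    loc <- locate_ring_ligands(seqc, span = span, spacing = spacing)
    if (is.null(loc)) next
    located <- c(located, pid)
    hits[[length(hits) + 1L]] <- data.frame(
      protein_id = pid, span_start = span[1L], span_end = span[2L],
      t(stats::setNames(loc$positions, paste0("pos", 1:8))),
      ligands = paste(loc$residues, collapse = ""),
      ring_class = classify_ring(loc$residues), stringsAsFactors = FALSE)
  }
  hit_df <- if (length(hits)) do.call(rbind, hits) else NULL
  if (!is.null(hit_df)) hit_df <- hit_df[!duplicated(hit_df$protein_id), , drop = FALSE]
  list(hits = hit_df,
       signature_only = setdiff(unique(attempted), unique(located)))
}

#' Collapse isoform ids to locus ids
#'
#' Strips a trailing `.n` isoform suffix (AGI convention) so set operations
#' run at locus level.
#'
#' @param ids character vector of protein/gene ids.
#' @return Character vector of locus ids.
#' @export
collapse_isoforms <- function(ids) {
  unique(sub("\\.\\d+$", "", ids))
}

#' Reconcile gene sets between genome releases
#'
#' Partitions an old gene set against a newly curated one: ids present in
#' both are `matched`; old ids missing from the new set are `dropped` with a
#' reason looked up from the evidence table (one of `merged`,
#' `no-RING-domain`, `absent-from-db`, `pseudogene`, `split-new-locus`,
#' `transposable-element`; unmatched ids without evidence are
#' `unresolved`); new ids not in the old set are `newly_identified`.
#'
#' @param new_ids,old_ids character vectors of locus ids.
#' @param evidence data.frame with columns `id`, `reason` for dropped ids.
#' @return Object of class `reconciliation_report`: list with `matched`,
#'   `newly_identified`, `dropped` (data.frame id/reason), and `counts`.
#' @export
reconcile <- function(new_ids, old_ids, evidence = NULL) {
  new_ids <- unique(new_ids)
  old_ids <- unique(old_ids)
  matched <- intersect(old_ids, new_ids)
  gone <- setdiff(old_ids, new_ids)
  reasons <- c("merged", "no-RING-domain", "absent-from-db", "pseudogene",
               "split-new-locus", "transposable-element")
  reason_of <- function(id) {
    if (!is.null(evidence) && id %in% evidence$id) {
      r <- evidence$reason[match(id, evidence$id)]
      if (!r %in% reasons) stop("unknown reason code for ", id, ": ", r)
      r
    } else "unresolved"
  }
  dropped <- data.frame(id = gone,
                        reason = vapply(gone, reason_of, character(1)),
                        stringsAsFactors = FALSE, row.names = NULL)
  stopifnot(length(matched) + nrow(dropped) == length(old_ids))
  counts <- c(matched = length(matched),
              dropped = nrow(dropped),
              newly_identified = length(setdiff(new_ids, old_ids)),
              table(factor(dropped$reason, levels = c(reasons, "unresolved"))))
  structure(list(matched = matched,
                 newly_identified = setdiff(new_ids, old_ids),
                 dropped = dropped, counts = counts),
            class = "reconciliation_report")
}

#' @export
print.reconciliation_report <- function(x, ...) {
  cat("<reconciliation_report>\n")
  print(x$counts)
  invisible(x)
}
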