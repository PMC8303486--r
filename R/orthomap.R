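#' Index peptide identifications by gene
#'
#' Resolves each identified database entry to its gene: canonical entries
#' through the UniProt idmapping table (unresolvable accessions are logged
#' and skipped; more than 50% unresolvable is treated as a mismatched
#' idmapping file and raises an error), peptide entries through the gene ids
#' encoded in the custom database. Canonical/noncanonical status is carried
#' through.
#'
#' @param ids identification table (see [read_identifications()]).
#' @param db the species' `custom_db`.
#' @param idmap idmapping table (see [load_id_mapping()]).
#' @return object of class `gene_peptide_index`: list with `taxon` and
#'   `entries`, a data.frame (`peptide`, `gene_id`, `proteoform_id`,
#'   `status`, `sample_group`, `spectral_count`).
#' @export
index_identifications <- function(ids, db, idmap) {
  stopifnot(inherits(db, "custom_db"))
  acc2gene <- setNames(idmap$gene_id, idmap$accession)
  pep_ids <- db$peptides$entry_id
  can_ids <- db$canonical$proteoform_id
  rows <- list()
  unresolved <- 0L; total_can <- 0L
  for (i in seq_len(nrow(ids))) {
    eid <- ids$db_entry_id[i]
    if (eid %in% can_ids) {
      total_can <- total_can + 1L
      gene <- acc2gene[eid]
      if (is.na(gene)) { unresolved <- unresolved + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = ids$peptide[i], gene_id = unname(gene),
        proteoform_id = eid, status = "canonical",
        sample_group = ids$sample_group[i],
        spectral_count = ids$spectral_count[i], stringsAsFactors = FALSE)
    } else if (eid %in% pep_ids) {
      j <- match(eid, pep_ids)
      parents <- db$peptides$parents[[j]]
      genes <- db$peptides$genes[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = ids$peptide[i], gene_id = genes,
        proteoform_id = parents, status = "noncanonical",
        sample_group = ids$sample_group[i],
        spectral_count = ids$spectral_count[i], stringsAsFactors = FALSE)
    } else {
      stop("identification references unknown database entry '", eid, "'",
           call. = FALSE)
    }
  }
  if (total_can > 0L && unresolved / total_can > 0.5)
    stop(unresolved, "/", total_can, " canonical accessions unresolved; ",
         "idmapping table likely does not match the database", call. = FALSE)
  if (unresolved > 0L)
    message("index_identifications: ", unresolved,
            " canonical accession(s) not in idmapping, skipped")
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(0), gene_id = character(0),
               proteoform_id = character(0), status = character(0),
               sample_group = character(0), spectral_count = integer(0))
  # aggregate duplicate (peptide, proteoform, group) rows
  key <- paste(entries$peptide, entries$proteoform_id, entries$sample_group,
               sep = "\r")
  agg <- tapply(entries$spectral_count, key, sum)
  entries <- entries[!duplicated(key), , drop = FALSE]
  entries$spectral_count <- as.integer(agg[paste(
    entries$peptide, entries$proteoform_id, entries$sample_group,
    sep = "\r")])
  entries <- entries[order(entries$peptide, entries$proteoform_id,
                           entries$sample_group), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(taxon = db$taxon, entries = entries),
            class = "gene_peptide_index")
}

#' @export
print.gene_peptide_index <- function(x, ...) {
  cat(sprintf("<gene_peptide_index> taxon %d: %d peptides on %d genes\n",
              x$taxon, length(unique(x$entries$peptide)),
              length(unique(x$entries$gene_id))))
  invisible(x)
}

# orient an ortholog table so taxon_a matches idx_a
orient_orthologs <- function(orth, taxon_a, taxon_b) {
  if (nrow(orth) == 0L) return(orth)
  if (orth$taxon_a[1L] == taxon_a && orth$taxon_b[1L] == taxon_b) return(orth)
  if (orth$taxon_a[1L] == taxon_b && orth$taxon_b[1L] == taxon_a) {
    return(data.frame(taxon_a = orth$taxon_b, gene_a = orth$gene_b,
                      taxon_b = orth$taxon_a, gene_b = orth$gene_a,
                      relationship = orth$relationship,
                      stringsAsFactors = FALSE))
  }
  stop("ortholog table taxa do not match the identification indexes",
       call. = FALSE)
}

#' Orthologous gene pairs with identified peptides in both species
#'
#' Returns every `(gene_a, gene_b)` pair of the ortholog table where both
#' genes carry at least one identified peptide in the respective index.
#' Equivalent to a brute-force nested-loop join.
#'
#' @param idx_a,idx_b per-species [index_identifications()] results.
#' @param orth ortholog table (see [load_gene_orthologs()]).
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
find_orthologous_genes <- function(idx_a, idx_b, orth) {
  orth <- orient_orthologs(orth, idx_a$taxon, idx_b$taxon)
  ga <- unique(idx_a$entries$gene_id)
  gb <- unique(idx_b$entries$gene_id)
  hit <- orth$gene_a %in% ga & orth$gene_b %in% gb
  out <- unique(data.frame(gene_a = orth$gene_a[hit],
                           gene_b = orth$gene_b[hit],
                           stringsAsFactors = FALSE))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Is a peptide proteotypic in a custom database?
#'
#' A peptide is proteotypic when it occurs as a substring of exactly one
#' database entry's underlying proteoform sequence. Peptide entries count as
#' their parent proteoform: when the database carries the full noncanonical
#' parent sequences in memory those are scanned; after a FASTA round trip
#' the peptide entries grouped by parent stand in for the parent sequence.
#'
#' @param peptide amino-acid string.
#' @param db a `custom_db`.
#' @return `TRUE` or `FALSE`; a peptide absent from every entry yields
#'   `FALSE` with a warning.
#' @export
is_proteotypic <- function(peptide, db) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  n <- 0L
  for (s in db$canonical$sequence) {
    if (grepl(peptide, s, fixed = TRUE)) {
      n <- n + 1L
      if (n > 1L) return(FALSE)
    }
  }
  if (!is.null(db$noncanonical_parents)) {
    for (s in db$noncanonical_parents) {
      if (grepl(peptide, s, fixed = TRUE)) {
        n <- n + 1L
        if (n > 1L) return(FALSE)
      }
    }
  } else if (nrow(db$peptides) > 0L) {
    parents <- unique(unlist(db$peptides$parents))
    for (p in parents) {
      has <- vapply(seq_len(nrow(db$peptides)), function(j)
        p %in% db$peptides$parents[[j]] &&
          grepl(peptide, db$peptides$sequence[j], fixed = TRUE),
        logical(1L))
      if (any(has)) {
        n <- n + 1L
        if (n > 1L) return(FALSE)
      }
    }
  }
  if (n == 0L) {
    warning("peptide '", peptide, "' absent from all database entries",
            call. = FALSE)
    return(FALSE)
  }
  n == 1L
}

#' Identical peptides shared by orthologous genes of two species
#'
#' Finds peptides whose exact sequence was identified in both species, whose
#' parent genes form a pair of the ortholog table, and whose
#' canonical/noncanonical status matches the filter. Per-species proteotypic
#' flags are computed from the databases; a peptide mapping to more than one
#' gene within a species is retained only when proteotypic in both species.
#'
#' @param idx_a,idx_b per-species [index_identifications()] results.
#' @param orth ortholog table.
#' @param status_filter `"canonical"`, `"noncanonical"` or `"any"`.
#' @param db_a,db_b the per-species custom databases (for proteotypic
#'   flags); when omitted the flags are `NA` and the multi-gene rule is not
#'   applied.
#' @return data.frame of hits: `peptide`, `gene_a`, `gene_b`,
#'   `proteoform_a`, `proteoform_b`, `status`, `proteotypic_a`,
#'   `proteotypic_b`, `spectral_count_a`, `spectral_count_b`,
#'   `sample_groups_a`, `sample_groups_b`.
#' @export
shared_identical_peptides <- function(idx_a, idx_b, orth,
                                      status_filter = c("noncanonical",
                                                        "canonical", "any"),
                                      db_a = NULL, db_b = NULL) {
  status_filter <- match.arg(status_filter)
  orth <- orient_orthologs(orth, idx_a$taxon, idx_b$taxon)
  ea <- idx_a$entries; eb <- idx_b$entries
  shared <- intersect(unique(ea$peptide), unique(eb$peptide))
  pair_key <- paste(orth$gene_a, orth$gene_b, sep = "\r")
  hits <- list()
  for (pep in sort(shared)) {
    sa <- ea[ea$peptide == pep, , drop = FALSE]
    sb <- eb[eb$peptide == pep, , drop = FALSE]
    if (status_filter != "any") {
      sa <- sa[sa$status == status_filter, , drop = FALSE]
      sb <- sb[sb$status == status_filter, , drop = FALSE]
    }
    if (nrow(sa) == 0L || nrow(sb) == 0L) next
    multi <- length(unique(sa$gene_id)) > 1L || length(unique(sb$gene_id)) > 1L
    pt_a <- if (!is.null(db_a)) is_proteotypic(pep, db_a) else NA
    pt_b <- if (!is.null(db_b)) is_proteotypic(pep, db_b) else NA
    if (multi && !is.null(db_a) && !is.null(db_b) &&
        !(isTRUE(pt_a) && isTRUE(pt_b))) next
    combos <- expand.grid(ia = which(!duplicated(paste(sa$gene_id,
                                                       sa$proteoform_id))),
                          ib = which(!duplicated(paste(sb$gene_id,
                                                       sb$proteoform_id))))
    for (r in seq_len(nrow(combos))) {
      ra <- sa[combos$ia[r], ]; rb <- sb[combos$ib[r], ]
      if (!paste(ra$gene_id, rb$gene_id, sep = "\r") %in% pair_key) next
      st <- if (ra$status == rb$status) ra$status else "mixed"
      hits[[length(hits) + 1L]] <- data.frame(
        peptide = pep, gene_a = ra$gene_id, gene_b = rb$gene_id,
        proteoform_a = ra$proteoform_id, proteoform_b = rb$proteoform_id,
        status = st, proteotypic_a = pt_a, proteotypic_b = pt_b,
        spectral_count_a = sum(sa$spectral_count[
          sa$proteoform_id == ra$proteoform_id]),
        spectral_count_b = sum(sb$spectral_count[
          sb$proteoform_id == rb$proteoform_id]),
        sample_groups_a = paste(sort(unique(sa$sample_group)), collapse = ";"),
        sample_groups_b = paste(sort(unique(sb$sample_group)), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(peptide = character(0), gene_a = character(0),
               gene_b = character(0), proteoform_a = character(0),
               proteoform_b = character(0), status = character(0),
               proteotypic_a = logical(0), proteotypic_b = logical(0),
               spectral_count_a = integer(0), spectral_count_b = integer(0),
               sample_groups_a = character(0), sample_groups_b = character(0))
  out <- out[order(out$peptide, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact intersection report over labeled sets
#'
#' Partitions the union of 2-6 labeled sets by exact membership signature
#' (UpSet-style): each item is assigned to the one subset matching the
#' groups that contain it, and counts over all signatures sum to the union
#' size.
#'
#' @param sets named list of 2-6 character vectors; names are group labels.
#' @return object of class `intersection_report`: list with `labels`,
#'   `table` (data.frame `subset`, `degree`, `count`, one row per non-empty
#'   signature combination) and `items` (named list of item vectors).
#' @export
intersection_report <- function(sets) {
  stopifnot(is.list(sets))
  if (length(sets) < 2L || length(sets) > 6L)
    stop("intersection_report needs 2-6 labeled sets", call. = FALSE)
  labels <- names(sets)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("all sets must be labeled", call. = FALSE)
  if (anyDuplicated(labels))
    stop("duplicate set labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  k <- length(labels)
  masks <- lapply(seq_len(2L^k - 1L), function(m) as.logical(bitwAnd(
    m, 2L^(seq_len(k) - 1L))))
  tab <- list(); items <- list()
  for (mask in masks) {
    sig <- paste(labels[mask], collapse = "&")
    if (length(universe) > 0L) {
      in_sub <- apply(member, 1L, function(row) all(row == mask))
    } else in_sub <- logical(0)
    tab[[length(tab) + 1L]] <- data.frame(
      subset = sig, degree = sum(mask), count = sum(in_sub),
      stringsAsFactors = FALSE)
    items[[sig]] <- universe[in_sub]
  }
  tab <- do.call(rbind, tab)
  tab <- tab[order(-tab$degree, tab$subset), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(labels = labels, table = tab, items = items),
            class = "intersection_report")
}

#' @export
print.intersection_report <- function(x, ...) {
  cat("<intersection_report> groups:", paste(x$labels, collapse = ", "),
      "| union size:", sum(x$table$count), "\n")
  print(x$table)
  invisible(x)
}
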