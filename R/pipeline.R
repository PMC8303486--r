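#' Run the full pipeline from a configuration file
#'
#' Orchestrates the stages of the proteogenomic workflow in order:
#' database construction for each species, cross-species ortholog peptide
#' mapping with intersection reports, and iTRAQ differential abundance
#' statistics. Inputs are checked before any stage runs; a stage failure
#' aborts with the stage named and that stage's partial outputs removed.
#' A `manifest.json` records the configuration snapshot, input/output file
#' checksums, row counts, package version and timestamps. Outputs are
#' deterministic for identical configuration and inputs (the manifest's
#' timestamps aside).
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Expected keys: `out_dir`; `species_a`/`species_b` each with
#'   `taxon`, `gtf`, `cds_fasta`, `canonical_fasta`, `idmapping`,
#'   `identifications` (vector of TSV paths); `orthologs`; optional `quant`
#'   with `table`, `control`, `case`; optional `digest`
#'   (`max_missed_cleavages`, `min_length`, `max_length`, `collapse_il`),
#'   `nmd_threshold`, `status`.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (k in c("out_dir", "species_a", "species_b", "orthologs"))
    if (is.null(cfg[[k]]))
      stop("pipeline config lacks required key '", k, "'", call. = FALSE)

  inputs <- c(
    unlist(lapply(c("species_a", "species_b"), function(sp)
      c(cfg[[sp]]$gtf, cfg[[sp]]$cds_fasta, cfg[[sp]]$canonical_fasta,
        cfg[[sp]]$idmapping, cfg[[sp]]$identifications))),
    cfg$orthologs, cfg$quant$table)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("pipeline pre-flight: missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dcfg <- digest_config(
    max_missed_cleavages = cfg$digest$max_missed_cleavages %||% 2L,
    min_peptide_length = cfg$digest$min_length %||% 6L,
    max_peptide_length = cfg$digest$max_length %||% 45L,
    collapse_IL = cfg$digest$collapse_il %||% FALSE)
  ncfg <- nmd_config(cfg$nmd_threshold %||% 50L)

  outputs <- character(0)
  counts <- list()
  stage <- function(name, outs, fun) {
    paths <- file.path(out_dir, outs)
    tryCatch(fun(paths), error = function(e) {
      unlink(paths[file.exists(paths)])
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    outputs <<- c(outputs, paths)
    paths
  }

  dbs <- list(); idxs <- list(); idtabs <- list()
  for (sp in c("species_a", "species_b")) {
    scfg <- cfg[[sp]]
    stage(paste0("build-db:", sp),
          c(paste0(sp, "_custom_db.fasta"), paste0(sp, "_db_report.tsv")),
          function(paths) {
            txs <- load_gtf(scfg$gtf)
            cds <- load_fasta(scfg$cds_fasta)
            canon <- load_canonical_proteome(scfg$canonical_fasta)
            res <- build_splice_db(txs, cds, canon, scfg$taxon, dcfg, ncfg)
            write_custom_db(res$db, paths[1L])
            write.table(res$report$transcripts, paths[2L], sep = "\t",
                        quote = FALSE, row.names = FALSE)
            dbs[[sp]] <<- res$db
            counts[[paste0(sp, "_db_entries")]] <<- db_n_entries(res$db)
          })
  }

  stage("orthomap",
        c("ortholog_peptide_hits.tsv", "peptide_intersections.tsv",
          "gene_intersections.tsv"),
        function(paths) {
          for (sp in c("species_a", "species_b")) {
            scfg <- cfg[[sp]]
            idmap <- load_id_mapping(scfg$idmapping, scfg$taxon)
            ids <- do.call(rbind, lapply(scfg$identifications,
                                         read_identifications))
            idtabs[[sp]] <<- ids
            idxs[[sp]] <<- index_identifications(ids, dbs[[sp]], idmap)
          }
          orth <- load_gene_orthologs(cfg$orthologs, cfg$species_a$taxon,
                                      cfg$species_b$taxon)
          hits <- shared_identical_peptides(
            idxs$species_a, idxs$species_b, orth,
            status_filter = cfg$status %||% "noncanonical",
            db_a = dbs$species_a, db_b = dbs$species_b)
          write.table(hits, paths[1L], sep = "\t", quote = FALSE,
                      row.names = FALSE)
          counts$ortholog_peptide_hits <<- nrow(hits)
          grp_sets <- function(col) {
            sets <- list()
            for (sp in c("species_a", "species_b")) {
              ids <- idtabs[[sp]]
              for (g in sort(unique(ids$sample_group))) {
                lab <- paste0(cfg[[sp]]$taxon, "-", g)
                ent <- idxs[[sp]]$entries
                sel <- ent$sample_group == g
                sets[[lab]] <- unique(ent[[col]][sel])
              }
            }
            sets
          }
          pep_rep <- intersection_report(grp_sets("peptide"))
          gene_rep <- intersection_report(grp_sets("gene_id"))
          write.table(pep_rep$table, paths[2L], sep = "\t", quote = FALSE,
                      row.names = FALSE)
          write.table(gene_rep$table, paths[3L], sep = "\t", quote = FALSE,
                      row.names = FALSE)
        })

  if (!is.null(cfg$quant$table)) {
    stage("quant", "peptide_abundance.tsv", function(paths) {
      qcfg <- quant_config(control_label = cfg$quant$control %||% "117",
                           case_label = cfg$quant$case %||% "118")
      tab <- read_quant_table(cfg$quant$table)
      res <- test_peptide_ratios(tab, qcfg)
      write.table(res, paths[1L], sep = "\t", quote = FALSE,
                  row.names = FALSE)
      counts$quantified_peptides <<- nrow(res)
    })
  }

  manifest <- list(
    tool = "orthosplice", version = as.character(packageVersion("orthosplice")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(md5sum(p)),
           rows = length(readLines(p, warn = FALSE)))),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
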