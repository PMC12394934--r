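# End-to-end orchestration: synthetic population generation and the full
# ingest -> filter -> properties -> composition -> positions -> motifs ->
# stats report bundle, driven by a single config list.

.write_table_meta <- function(df, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata))
    writeLines(sprintf("# %s: %s", names(metadata),
                       vapply(metadata, paste, "", collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Generate synthetic digestion + enrichment peptide reports
#'
#' Simulates the study design: proteins (from a FASTA, or random
#' rice-bran-like proteins when none is given) are digested under two
#' schemes — sequential pepsin then trypsin, and papain — and each
#' digest is passed over a simulated Cu(II)-IMAC column whose retention
#' model is calibrated so that the expected frequency of N-terminal
#' histidine among retained peptides matches `target_his_n1`.
#' Identification probabilities are drawn mostly above 0.99, emulating
#' a filtered search report. Writes one report per condition and
#' fraction plus a JSON manifest of all generating parameters.
#'
#' @param config List with any of: `fasta` (path; optional),
#'   `n_proteins` (default 40, used when no FASTA), `seed` (default 1),
#'   `out_dir` (required), `target_his_n1` (default 0.32),
#'   `feature_retention` (N1-His capture boost, default 0.999),
#'   `w_his_count`, `w_gly_frac`, `w_pro_frac` (composition weights of
#'   the retention model; defaults 1.2, 16, 15 emulate the elevated
#'   His/Gly/Pro content of IMAC eluents), `max_missed_cleavages`
#'   (default 2), `min_length` (default 5), `max_length` (default 30).
#' @return Invisibly, a list with the populations and the manifest.
#' @export
run_synthetic <- function(config) {
  cfg <- utils::modifyList(
    list(fasta = NULL, n_proteins = 40L, seed = 1L,
         target_his_n1 = 0.32, feature_retention = 0.999,
         w_his_count = 1.2, w_gly_frac = 16, w_pro_frac = 15,
         max_missed_cleavages = 2L, min_length = 5L, max_length = 30L),
    config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  proteins <- .stage("proteins", {
    if (!is.null(cfg$fasta)) read_fasta(cfg$fasta)
    else random_proteins(cfg$n_proteins, seed = cfg$seed)
  })

  mk_rule <- function(enzyme, missed = cfg$max_missed_cleavages)
    enzyme_rule(enzyme, max_missed_cleavages = missed,
                min_length = cfg$min_length, max_length = cfg$max_length)
  digests <- .stage("digestion", list(
    pep_tryp = digest_proteins(
      proteins,
      list(enzyme_rule("pepsin",
                       max_missed_cleavages = cfg$max_missed_cleavages,
                       min_length = 1L),
           mk_rule("trypsin")),
      condition = "pep_tryp"),
    papain = digest_proteins(proteins, mk_rule("papain"),
                             condition = "papain")))

  out <- list()
  manifest <- list(parameters = cfg[setdiff(names(cfg),
                                            c("fasta", "out_dir"))],
                   fasta = if (is.null(cfg$fasta)) "random" else cfg$fasta,
                   counts = list())
  for (cond in names(digests)) {
    pop <- digests[[cond]]
    pop$fraction <- "RBPH"
    pop$probability <- withr_seed(
      cfg$seed + match(cond, names(digests)),
      pmin(1, round(1 - stats::rexp(nrow(pop), rate = 200), 4)))
    base <- enrichment_model(w_his_count = cfg$w_his_count,
                             w_gly_frac = cfg$w_gly_frac,
                             w_pro_frac = cfg$w_pro_frac)
    model <- .stage("calibration",
                    calibrate_enrichment(pop, cfg$target_his_n1,
                                         feature = "his_n1",
                                         feature_retention = cfg$feature_retention,
                                         base_model = base,
                                         seed = cfg$seed + 100L +
                                           match(cond, names(digests))))
    split <- .stage("enrichment", simulate_enrichment(pop, model))
    files <- list(RBPH = pop, retained = split$retained,
                  flow_through = split$flow_through)
    for (nm in names(files)) {
      path <- file.path(cfg$out_dir, sprintf("%s_%s.tsv", cond, nm))
      write_peptide_report(files[[nm]], path,
                           metadata = list(condition = cond, fraction = nm,
                                           seed = cfg$seed))
    }
    manifest$counts[[cond]] <- list(
      digested = nrow(pop), retained = nrow(split$retained),
      flow_through = nrow(split$flow_through))
    manifest$calibration[[cond]] <- c(list(intercept = model$intercept),
                                      as.list(model$weights))
    out[[cond]] <- c(list(RBPH = pop), split)
  }
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "synth_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(populations = out, manifest = manifest))
}

#' Run the full peptide-population profiling pipeline
#'
#' Ingests one or more peptide reports, applies the probability filter,
#' and writes the full report bundle: per-peptide properties, global
#' composition with enrichment ratios against a background profile,
#' positional matrices (pooled and per condition), motif catalogues and
#' cross-condition pairs for each window length, between-condition
#' property statistics, and a JSON run manifest with per-stage counts.
#' Identical config + inputs produce byte-identical outputs.
#'
#' @param config List with: `inputs` (character vector of report paths,
#'   required), `out_dir` (required), and optionally
#'   `probability_threshold` (default 0.99), `pka` (default
#'   `"emboss"`), `background` (path to a background profile TSV;
#'   default the shipped rice-bran profile), `motif_n` (default
#'   `c(5, 6, 7)`), `min_count` (default 2), `top_k` (default 50),
#'   `max_distance` (default 0.4), `min_length` (default 5, positional
#'   analysis), `column_map`, `seed` (default 1).
#' @return Invisibly, a list with the filtered population and the
#'   manifest.
#' @export
run_profile <- function(config) {
  cfg <- utils::modifyList(
    list(probability_threshold = 0.99, pka = "emboss", background = NULL,
         motif_n = c(5L, 6L, 7L), min_count = 2L, top_k = 50L,
         max_distance = 0.4, min_length = 5L, column_map = NULL,
         seed = 1L),
    config)
  if (is.null(cfg$inputs) || is.null(cfg$out_dir))
    stop("config$inputs and config$out_dir are required", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  pka <- pka_set(cfg$pka)
  meta_common <- list(probability_threshold = cfg$probability_threshold,
                      pka_set = pka$name, seed = cfg$seed)

  pops <- .stage("ingest",
                 lapply(cfg$inputs, read_peptide_report,
                        column_map = cfg$column_map))
  pop <- .stage("ingest", {
    merged <- do.call(rbind, lapply(pops, as.data.frame))
    peptide_population(merged$sequence, merged$protein_id,
                       merged$probability, merged$condition,
                       merged$fraction, label = "merged")
  })
  n_in <- nrow(pop)

  filtered <- .stage("probability_filter",
                     filter_by_probability(pop, cfg$probability_threshold))
  n_filtered <- nrow(filtered)
  if (!n_filtered)
    stop("pipeline stage 'probability_filter' left no peptides",
         call. = FALSE)

  props <- .stage("properties", peptide_properties(filtered, pka = pka))
  .write_table_meta(
    cbind(props, condition = filtered$condition),
    file.path(cfg$out_dir, "properties.tsv"), meta_common)

  comp <- .stage("composition", global_composition(filtered))
  background <- .stage("composition", {
    if (is.null(cfg$background)) rice_bran_background()
    else read_background_profile(cfg$background)
  })
  .write_table_meta(
    data.frame(residue = amino_acids(),
               percent = as.numeric(unclass(comp)[amino_acids()]),
               background = as.numeric(background[amino_acids()]),
               enrichment_ratio = as.numeric(
                 enrichment_ratio(comp, background))),
    file.path(cfg$out_dir, "composition.tsv"),
    c(meta_common, list(total_residues = attr(comp, "total_residues"))))

  mats <- .stage("positions",
                 positional_matrix_by_condition(filtered,
                                                min_length = cfg$min_length))
  for (nm in names(mats))
    write_positional_matrix(mats[[nm]],
                            file.path(cfg$out_dir,
                                      sprintf("positions_%s.tsv", nm)),
                            metadata = c(meta_common, list(condition = nm)))

  conds <- unique(filtered$condition)
  motif_counts <- list()
  for (N in cfg$motif_n) {
    cat_n <- .stage("motifs",
                    build_catalog(filtered, N, min_count = cfg$min_count))
    write_catalog(cat_n,
                  file.path(cfg$out_dir, sprintf("motifs_N%d.tsv", N)),
                  metadata = meta_common)
    motif_counts[[as.character(N)]] <- nrow(cat_n$counts)
    if (length(conds) >= 2L) {
      pairs <- .stage("motifs",
                      cross_condition_compare(cat_n, top_k = cfg$top_k,
                                              max_distance = cfg$max_distance))
      .write_table_meta(pairs,
                        file.path(cfg$out_dir, sprintf("pairs_N%d.tsv", N)),
                        c(meta_common, list(top_k = cfg$top_k,
                                            max_distance = cfg$max_distance)))
    }
  }

  stats_tab <- NULL
  if (length(conds) >= 2L) {
    stats_tab <- .stage("stats", {
      rows <- list()
      for (i in seq_len(length(conds) - 1L))
        for (j in (i + 1L):length(conds)) {
          cmp <- compare_all_properties(
            filtered[filtered$condition == conds[i], , drop = FALSE],
            filtered[filtered$condition == conds[j], , drop = FALSE],
            pka = pka)
          cmp$condition_a <- conds[i]; cmp$condition_b <- conds[j]
          rows[[length(rows) + 1L]] <- cmp
        }
      do.call(rbind, rows)
    })
    .write_table_meta(stats_tab, file.path(cfg$out_dir, "stats.tsv"),
                      meta_common)
  }

  manifest <- list(
    parameters = cfg[setdiff(names(cfg),
                             c("inputs", "column_map", "out_dir"))],
    inputs = cfg$inputs,
    counts = list(ingested = n_in,
                  dropped_missing_probability =
                    attr(filtered, "n_dropped_missing"),
                  dropped_below_threshold =
                    attr(filtered, "n_dropped_below"),
                  analyzed = n_filtered,
                  excluded_short_positional =
                    attr(mats$pooled, "n_excluded"),
                  motifs_kept = motif_counts),
    conditions = as.list(table(filtered$condition)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(population = filtered, properties = props,
                 matrices = mats, stats = stats_tab, manifest = manifest))
}
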