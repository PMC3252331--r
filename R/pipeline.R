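#' Configuration for a full marker-evaluation run
#'
#' @param marker_paths named character vector: marker name -> FASTA path.
#' @param combinations list of character vectors of marker names to evaluate
#'   as concatenations (default: every pair plus the full combination when
#'   more than one marker is declared).
#' @param policy a [filter_policy()].
#' @param model distance model for the tree (`"JC"`, as is usual for NJ
#'   barcode trees) — the overall-distance column always uses K2P.
#' @param tree_markers markers to concatenate for the tree stage (default:
#'   all declared markers).
#' @param bootstrap_replicates NJ bootstrap pseudoreplicates (default 1000).
#' @param outgroup specimen id used to root the tree, excluded from
#'   identification; `NULL` disables the tree stage's rooting-dependent
#'   monophyly summary.
#' @param query_mode passed to [identify_species()].
#' @param id_sep FASTA header separator (see [read_marker_fasta()]).
#' @param bin_width histogram bin width (default 0.005).
#' @param out_dir output directory.
#' @param seed seed for the bootstrap stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(marker_paths,
                       combinations = NULL,
                       policy = filter_policy(),
                       model = "JC",
                       tree_markers = NULL,
                       bootstrap_replicates = 1000,
                       outgroup = NULL,
                       query_mode = "per_sequence",
                       id_sep = "|",
                       bin_width = 0.005,
                       out_dir = "barcodegauge_run",
                       seed = 1) {
  if (length(marker_paths) < 1L || is.null(names(marker_paths)) ||
      any(names(marker_paths) == "")) {
    stop("marker_paths must be a named vector of at least one FASTA path")
  }
  markers <- names(marker_paths)
  if (is.null(combinations)) {
    combinations <- list()
    if (length(markers) > 1L) {
      combinations <- utils::combn(markers, 2, simplify = FALSE)
      if (length(markers) > 2L) {
        combinations <- c(combinations, list(markers))
      }
    }
  }
  for (cmb in combinations) {
    bad <- setdiff(cmb, markers)
    if (length(bad) > 0L) {
      stop("combination references undeclared marker(s): ",
           paste(bad, collapse = ", "))
    }
    if (length(cmb) < 2L) stop("combinations must list at least 2 markers")
  }
  tree_markers <- tree_markers %||% markers
  bad <- setdiff(tree_markers, markers)
  if (length(bad) > 0L) {
    stop("tree_markers references undeclared marker(s): ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(marker_paths = marker_paths, combinations = combinations,
         policy = policy, model = model, tree_markers = tree_markers,
         bootstrap_replicates = bootstrap_replicates, outgroup = outgroup,
         query_mode = query_mode, id_sep = id_sep, bin_width = bin_width,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full marker-evaluation pipeline
#'
#' Stages: read + filter each marker; per-marker K2P distance matrices,
#' overall distances and distance histograms (all three scopes); best-match
#' identification per marker and per declared combination; NJ tree with
#' bootstrap support on the concatenated tree markers; species/genus
#' monophyly summary on the outgroup-rooted tree. Every table is written as
#' TSV and all numbers are collected into one `summary.json`. Runs are
#' deterministic given the seed and inputs (the JSON is byte-identical
#' across repeated runs).
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `success`, `overall_k2p`, `ts_tv`,
#'   `histograms`, `tree`, `monophyly`, `filter_log`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in config$marker_paths) {
    if (!file.exists(p)) stop("input file missing: ", p)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[barcodegauge] ", sprintf(...))

  ## stage 1: read + filter -------------------------------------------------
  mats <- list()
  filter_log <- list()
  for (nm in names(config$marker_paths)) {
    raw <- read_marker_fasta(config$marker_paths[[nm]], marker = nm,
                             id_sep = config$id_sep)
    fl <- filter_records(raw, config$policy)
    if (is.null(fl$matrix)) stop("stage filter: no records left for marker ", nm)
    mats[[nm]] <- fl$matrix
    filter_log[[nm]] <- fl$log
    log_stage("filter %s: %d in, %d removed, %d retained", nm,
              n_sequences(raw), nrow(fl$log), n_sequences(fl$matrix))
    stopifnot(nrow(fl$log) + n_sequences(fl$matrix) == n_sequences(raw))
  }
  filter_log <- do.call(rbind, c(
    Map(function(nm, lg) if (nrow(lg)) cbind(marker = nm, lg) else NULL,
        names(filter_log), filter_log),
    list(make.row.names = FALSE)
  ))
  if (is.null(filter_log)) {
    filter_log <- data.frame(marker = character(0), specimen_id = character(0),
                             species = character(0), reason = character(0))
  }
  write_filter_log(filter_log, file.path(config$out_dir, "filter_log.tsv"))

  ing <- function(mm) {
    if (is.null(config$outgroup)) return(mm)
    keep <- specimen_ids(mm) != config$outgroup
    marker_matrix(mm$seqs[keep], mm$species[keep], marker = mm$marker)
  }

  ## stage 2: distances -----------------------------------------------------
  overall_k2p <- numeric(0)
  ts_tv <- numeric(0)
  histograms <- list()
  for (nm in names(mats)) {
    m <- ing(mats[[nm]])
    dm <- distance_matrix(m, "K2P")
    write_distance_tsv(dm, file.path(config$out_dir, paste0("dist_k2p_", nm, ".tsv")))
    overall_k2p[nm] <- overall_mean_distance(dm)
    ts_tv[nm] <- tryCatch(ts_tv_ratio(m), error = function(e) NA_real_)
    histograms[[nm]] <- lapply(
      stats::setNames(nm = c("all", "interspecific", "intraspecific")),
      function(sc) {
        h <- withCallingHandlers(
          distance_histogram(dm, species_map(m), scope = sc,
                             bin_width = config$bin_width),
          warning = function(w) invokeRestart("muffleWarning"))
        utils::write.table(h, file.path(config$out_dir,
                                        sprintf("hist_%s_%s.tsv", nm, sc)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        h
      })
    log_stage("distances %s: overall K2P = %.4f", nm, overall_k2p[nm])
  }

  ## stage 3: identification ------------------------------------------------
  sets <- c(stats::setNames(as.list(names(mats)), names(mats)),
            stats::setNames(config$combinations,
                            vapply(config$combinations, paste, character(1),
                                   collapse = "+")))
  reports <- list()
  for (nm in names(sets)) {
    mm <- if (length(sets[[nm]]) == 1L) {
      mats[[sets[[nm]]]]
    } else {
      concatenate_markers(mats[sets[[nm]]], name = nm)
    }
    mm <- ing(mm)
    reports[[nm]] <- identify_species(build_library(mm),
                                      query_mode = config$query_mode)
    write_identification_report(
      reports[[nm]],
      tsv_path = file.path(config$out_dir, paste0("identification_", nm, ".tsv")))
    log_stage("identify %s: %d/%d species (%.2f%%)", nm,
              reports[[nm]]$n_success, reports[[nm]]$n_species,
              reports[[nm]]$success_rate)
  }
  succ <- success_table(reports, overall_k2p = overall_k2p)
  utils::write.table(succ, file.path(config$out_dir, "success_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 4: tree + monophyly ----------------------------------------------
  tree_mat <- if (length(config$tree_markers) == 1L) {
    mats[[config$tree_markers]]
  } else {
    concatenate_markers(mats[config$tree_markers])
  }
  tree <- withCallingHandlers(
    bootstrap_support(tree_mat, model = config$model,
                      replicates = config$bootstrap_replicates,
                      seed = config$seed),
    warning = function(w) {
      log_stage("bootstrap: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  ape::write.tree(tree, file.path(config$out_dir, "nj_tree.nwk"))
  log_stage("tree: %d tips, %d bootstrap replicates used",
            length(tree$tip.label), attr(tree, "replicates_used"))

  mono <- NULL
  if (!is.null(config$outgroup)) {
    mono <- monophyly_summary(tree, species_map(tree_mat), config$outgroup)
    write_monophyly_tsv(mono, file.path(config$out_dir, "monophyly.tsv"))
    log_stage("monophyly: %d species, %d genera monophyletic",
              mono$n_species_monophyletic, mono$n_genera_monophyletic)
  }

  ## stage 5: machine-readable summary --------------------------------------
  supports <- tree$node.label[!is.na(tree$node.label)]
  summary <- list(
    markers = names(mats),
    n_sequences = lapply(mats, n_sequences),
    overall_k2p = as.list(overall_k2p),
    ts_tv = as.list(ts_tv),
    identification = lapply(reports, function(r) {
      list(n_species = r$n_species, n_success = r$n_success,
           success_rate = r$success_rate)
    }),
    tree = list(
      n_tips = length(tree$tip.label),
      bootstrap_replicates_used = attr(tree, "replicates_used"),
      mean_support = if (length(supports)) mean(supports) else NA,
      supports_ge_50 = sum(supports >= 50)
    ),
    monophyly = if (is.null(mono)) NULL else list(
      n_species_tested = nrow(mono$species),
      n_species_monophyletic = mono$n_species_monophyletic,
      n_genera_tested = nrow(mono$genera),
      n_genera_monophyletic = mono$n_genera_monophyletic
    ),
    seed = config$seed
  )
  json_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  log_stage("summary written to %s", json_path)

  invisible(list(success = succ, overall_k2p = overall_k2p, ts_tv = ts_tv,
                 histograms = histograms, tree = tree, monophyly = mono,
                 filter_log = filter_log,
                 paths = list(out_dir = config$out_dir, summary = json_path)))
}
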