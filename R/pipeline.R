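## Batch audit of a directory of models with target/group stratification.

#' Parse a CASP model identifier
#'
#' CASP RNA submissions are named `R<target>TS<group>_<index>`
#' (e.g. `R1107TS416_2`).
#'
#' @param model_id model identifier string.
#' @return list with `target_id` (e.g. `"R1107"`), `group_id` (e.g.
#'   `"TS416"`), `index`; `NA` fields when the id does not match.
#' @export
parse_casp_model_id <- function(model_id) {
  m <- regmatches(model_id,
                  regexec("^(R[0-9]+[a-z]?)(TS[0-9]+)_([0-9]+)", model_id))[[1]]
  if (!length(m)) return(list(target_id = NA_character_,
                              group_id = NA_character_, index = NA_integer_))
  list(target_id = m[2], group_id = m[3], index = as.integer(m[4]))
}

#' Packaged CASP15 target metadata
#'
#' The 12 CASP15 RNA targets with their natural/synthetic class and
#' assessor difficulty.
#'
#' @return data frame with `target_id`, `length_nt`, `target_class`,
#'   `difficulty`.
#' @export
casp_targets <- function() {
  utils::read.csv(system.file("extdata", "casp15_targets.csv",
                              package = "rnatangle"),
                  stringsAsFactors = FALSE)
}

#' Packaged CASP15 group metadata
#'
#' Prediction groups with method class (traditional or ML) and participant
#' class (server or human). The shipped table covers the groups documented
#' in the package sources; extend the CSV to cover a full cohort.
#'
#' @return data frame with `group_id`, `group_name`, `method_class`,
#'   `participant_class`.
#' @export
casp_groups <- function() {
  utils::read.csv(system.file("extdata", "casp15_groups.csv",
                              package = "rnatangle"),
                  stringsAsFactors = FALSE)
}

#' Audit one model file
#'
#' Reads the model, checks for duplicated coordinates, detects entanglements
#' of structure elements, and assesses each chain for backbone knots.
#'
#' @param path model file (PDB/mmCIF).
#' @param ss_source `"detect"` for geometric pair detection or
#'   `"dotbracket"` to read a `.dbn` sidecar next to the model file.
#' @param n_closures,crossing_budget,seed knot protocol parameters, see
#'   [assess_knot()].
#' @param discard_ambiguous treat probabilistically-knotted chains whose
#'   direct closure is an unknot as unknotted.
#' @param metadata optional list with `targets` and `groups` data frames.
#' @return a `model_report`: model/target/group ids, `status`
#'   (`ok`/`invalid-coordinates`/`ttc`/`error`), `entanglements` (list),
#'   `entanglement_table`, `knot` (list of per-chain `knot_assessment`),
#'   `entangled_elements`, `knotted` flags.
#' @export
audit_model <- function(path, ss_source = c("detect", "dotbracket"),
                        n_closures = 200, crossing_budget = 50, seed = 1,
                        discard_ambiguous = FALSE, metadata = NULL) {
  ss_source <- match.arg(ss_source)
  model <- read_model(path)
  ids <- parse_casp_model_id(model$model_id)
  report <- list(model_id = model$model_id,
                 target_id = ids$target_id, group_id = ids$group_id,
                 status = "ok", entanglements = list(),
                 knot = list(), entangled_elements = FALSE, knotted = FALSE,
                 ttc = FALSE, invalid_coordinates = FALSE,
                 dominant_knot = NA_character_)
  class(report) <- "model_report"
  dup <- detect_duplicate_coordinates(model)
  if (nrow(dup)) {
    report$status <- "invalid-coordinates"
    report$invalid_coordinates <- TRUE
  }
  ss <- list()
  for (cid in names(model$chains)) {
    dbn <- paste0(tools::file_path_sans_ext(path), ".dbn")
    ss[[cid]] <- if (ss_source == "dotbracket" && file.exists(dbn)) {
      lines <- readLines(dbn, warn = FALSE)
      annotate_base_pairs(model, "dotbracket", dotbracket = lines[2],
                          chain_id = cid)
    } else {
      ## no sidecar: fall back to geometric detection
      annotate_base_pairs(model, "detect", chain_id = cid)
    }
  }
  report$entanglements <- detect_all(model, ss)
  report$entanglement_table <- entanglement_table(report$entanglements)
  report$entangled_elements <- length(report$entanglements) > 0
  if (!report$invalid_coordinates) {
    for (cid in names(model$chains)) {
      ka <- tryCatch(
        assess_knot(extract_backbone(model, cid), n_closures = n_closures,
                    crossing_budget = crossing_budget, seed = seed),
        invalid_coordinates = function(e) e,
        error = function(e) NULL)
      if (inherits(ka, "invalid_coordinates")) {
        report$status <- "invalid-coordinates"
        report$invalid_coordinates <- TRUE
        next
      }
      if (is.null(ka)) next
      report$knot[[cid]] <- ka
      chain_knotted <- ka$knotted && !(discard_ambiguous && ka$ambiguous)
      if (chain_knotted && !report$knotted) {
        report$knotted <- TRUE
        report$dominant_knot <- ka$dominant_label
      }
      if (ka$ttc) report$ttc <- TRUE
    }
    if (report$ttc && report$status == "ok") report$status <- "ttc"
  }
  if (!is.null(metadata)) report <- attach_metadata(report, metadata)
  report
}

attach_metadata <- function(report, metadata) {
  t <- metadata$targets
  g <- metadata$groups
  report$target_class <- NA_character_
  report$difficulty <- NA_character_
  report$method_class <- NA_character_
  report$participant_class <- NA_character_
  if (!is.null(t) && !is.na(report$target_id)) {
    hit <- match(report$target_id, t$target_id)
    if (!is.na(hit)) {
      report$target_class <- t$target_class[hit]
      report$difficulty <- t$difficulty[hit]
    }
  }
  if (!is.null(g) && !is.na(report$group_id)) {
    hit <- match(report$group_id, g$group_id)
    if (!is.na(hit)) {
      report$method_class <- g$method_class[hit]
      report$participant_class <- g$participant_class[hit]
    }
  }
  report
}

#' Audit a directory of models
#'
#' Runs [audit_model()] on every PDB/mmCIF file in a directory. Failures are
#' recorded per model (status `"error"`) and never abort the batch; results
#' are deterministic given the seed and independent of file order.
#'
#' @param models_dir directory of model files.
#' @param metadata list with `targets`/`groups` data frames; defaults to the
#'   packaged CASP15 tables.
#' @inheritParams audit_model
#' @return list of `model_report`s, sorted by model id.
#' @export
scan_models <- function(models_dir, metadata = NULL,
                        ss_source = c("detect", "dotbracket"),
                        n_closures = 200, crossing_budget = 50, seed = 1,
                        discard_ambiguous = FALSE) {
  ss_source <- match.arg(ss_source)
  if (!dir.exists(models_dir))
    stop("cannot read directory ", models_dir, call. = FALSE)
  files <- sort(list.files(models_dir, pattern = "\\.(pdb|ent|cif|mmcif)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(files)) {
    warning("no model files in ", models_dir, call. = FALSE)
    return(list())
  }
  if (is.null(metadata))
    metadata <- list(targets = tryCatch(casp_targets(), error = function(e) NULL),
                     groups = tryCatch(casp_groups(), error = function(e) NULL))
  reports <- lapply(files, function(f) {
    tryCatch(
      audit_model(f, ss_source = ss_source, n_closures = n_closures,
                  crossing_budget = crossing_budget, seed = seed,
                  discard_ambiguous = discard_ambiguous, metadata = metadata),
      error = function(e) {
        structure(list(model_id = tools::file_path_sans_ext(basename(f)),
                       target_id = NA_character_, group_id = NA_character_,
                       status = "error", error = conditionMessage(e),
                       entanglements = list(), knot = list(),
                       entangled_elements = FALSE, knotted = FALSE,
                       ttc = FALSE, invalid_coordinates = FALSE,
                       dominant_knot = NA_character_),
                  class = "model_report")
      })
  })
  reports[order(vapply(reports, function(r) r$model_id, character(1)))]
}

#' Summarize audited models by stratum
#'
#' Counts models, interlaces, lassos (per entanglement instance), trefoils,
#' other classified knots, and TTC models per stratum, plus the entanglement
#' probability (entangled models / models) and the only-elements / only-knots
#' / both decomposition.
#'
#' @param reports list of `model_report`s.
#' @param strata report field to stratify on (e.g. `"target_class"`,
#'   `"method_class"`, `"participant_class"`), or `NULL` for totals only.
#' @return object of class `cohort_summary`: `table` (one row per stratum
#'   plus a total row) and `venn` (`only_elements`, `only_knots`, `both`,
#'   `entangled_models`).
#' @export
summarize_reports <- function(reports, strata = NULL) {
  stratum_of <- function(r) {
    if (is.null(strata)) return("all")
    v <- r[[strata]]
    if (is.null(v) || is.na(v)) "unknown" else v
  }
  labels <- vapply(reports, stratum_of, character(1))
  if (!is.null(strata)) {
    known <- c("all", "unknown", "natural", "synthetic", "traditional", "ML",
               "server", "human", "easy", "medium", "difficult")
    bad <- setdiff(unique(labels), known)
    if (length(bad))
      stop("unknown stratum label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  one_stratum <- function(idx) {
    rs <- reports[idx]
    tabs <- lapply(rs, function(r) r$entanglement_table)
    tabs <- tabs[!vapply(tabs, is.null, logical(1))]
    et <- if (length(tabs)) do.call(rbind, tabs) else
      entanglement_table(list())
    interlaces <- sum(grepl("&", et$subclass, fixed = TRUE))
    lassos <- sum(!grepl("&", et$subclass, fixed = TRUE))
    knots <- vapply(rs, function(r)
      if (r$knotted) r$dominant_knot else NA_character_, character(1))
    data.frame(
      models = length(rs),
      interlaces = interlaces,
      lassos = lassos,
      trefoils = sum(knots == "3_1", na.rm = TRUE),
      other_knots = sum(!is.na(knots) & knots != "3_1"),
      ttc = sum(vapply(rs, function(r) isTRUE(r$ttc), logical(1))),
      entangled_models = sum(vapply(rs, function(r)
        r$entangled_elements || r$knotted, logical(1))),
      entanglement_probability = round(mean(vapply(rs, function(r)
        r$entangled_elements || r$knotted, logical(1))), 2))
  }
  groups <- split(seq_along(reports), labels)
  tab <- do.call(rbind, lapply(names(groups), function(g) {
    cbind(stratum = g, one_stratum(groups[[g]]))
  }))
  total <- cbind(stratum = "total", one_stratum(seq_along(reports)))
  tab <- rbind(tab, total)
  el <- vapply(reports, function(r) r$entangled_elements, logical(1))
  kn <- vapply(reports, function(r) r$knotted, logical(1))
  venn <- list(only_elements = sum(el & !kn), only_knots = sum(!el & kn),
               both = sum(el & kn), entangled_models = sum(el | kn))
  structure(list(table = tab, venn = venn, strata = strata),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>",
      if (!is.null(x$strata)) paste("by", x$strata) else "", "\n")
  print(x$table, row.names = FALSE)
  cat("only elements:", x$venn$only_elements,
      "| only knots:", x$venn$only_knots,
      "| both:", x$venn$both, "\n")
  invisible(x)
}

#' Write audit reports to disk
#'
#' Emits one JSON report per model, a flat entanglement CSV, a summary CSV
#' shaped like the by-stratum tables (columns Models, Interlaces, Lassos,
#' Trefoils, Other knots, TTC), and a machine-readable run manifest.
#'
#' @param reports list of `model_report`s.
#' @param summary a `cohort_summary`.
#' @param out_dir output directory (created if missing).
#' @param manifest named list of run parameters stored alongside.
#' @return invisibly, the paths written.
#' @export
write_reports <- function(reports, summary, out_dir, manifest = list()) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot write to ", out_dir, call. = FALSE)
  paths <- character(0)
  for (r in reports) {
    j <- file.path(out_dir, paste0(r$model_id, ".json"))
    jsonlite::write_json(report_to_list(r), j, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, j)
  }
  ecsv <- file.path(out_dir, "entanglements.csv")
  etab <- do.call(rbind, lapply(reports, function(r) {
    t <- r$entanglement_table
    if (is.null(t) || !nrow(t)) return(NULL)
    cbind(model = r$model_id, t)
  }))
  if (is.null(etab))
    etab <- cbind(model = character(0), entanglement_table(list()))
  utils::write.csv(etab, ecsv, row.names = FALSE)
  scsv <- file.path(out_dir, "summary.csv")
  st <- summary$table
  names(st) <- c("Stratum", "Models", "Interlaces", "Lassos", "Trefoils",
                 "Other knots", "TTC", "Entangled models",
                 "Entanglement probability")
  utils::write.csv(st, scsv, row.names = FALSE)
  man <- file.path(out_dir, "manifest.json")
  manifest$package_version <- as.character(utils::packageVersion("rnatangle"))
  manifest$venn <- summary$venn
  jsonlite::write_json(manifest, man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, ecsv, scsv, man))
}

report_to_list <- function(r) {
  list(model_id = r$model_id, target_id = r$target_id,
       group_id = r$group_id, status = r$status,
       entangled_elements = r$entangled_elements, knotted = r$knotted,
       ttc = r$ttc, dominant_knot = r$dominant_knot,
       entanglements = if (!is.null(r$entanglement_table) &&
                             nrow(r$entanglement_table))
         r$entanglement_table else list(),
       knot = lapply(r$knot, function(k) {
         list(chain_id = k$chain_id,
              closure_histogram = as.list(k$closure_histogram),
              dominant_label = k$dominant_label, knotted = k$knotted,
              ttc = k$ttc, direct_closure_label = k$direct_closure_label,
              ambiguous = k$ambiguous, n_completed = k$n_completed,
              n_exceeded = k$n_exceeded, seed = k$seed)
       }))
}
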