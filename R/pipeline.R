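#' Read sensorgram files (delimited text with concentration header)
#'
#' Each file holds one curve: comment lines starting `#` carry metadata,
#' one of which must be `# conc_M: <number>`; the body is two delimited
#' columns, time (s) and response (RU).
#'
#' @param paths Character vector of file paths.
#' @return Tibble `(time, response, conc, curve)`.
#' @export
read_sensorgrams <- function(paths) {
  purrr::imap_dfr(paths, function(p, i) {
    if (!file.exists(p)) rlang::abort(paste0("sensorgram file not found: ", p))
    lines <- readLines(p)
    hdr <- grep("^#\\s*conc_M:", lines, value = TRUE)
    if (length(hdr) != 1)
      rlang::abort(paste0("missing '# conc_M:' header in ", p))
    conc <- as.numeric(sub("^#\\s*conc_M:\\s*", "", hdr))
    body <- utils::read.table(text = lines[!grepl("^#", lines)],
                              col.names = c("time", "response"))
    tibble(time = body$time, response = body$response, conc = conc, curve = i)
  })
}

#' Write sensorgrams to per-curve delimited files
#' @param data Tibble with `time`, `response`, `conc` (and optionally
#'   `curve`).
#' @param dir Output directory.
#' @return The written paths, invisibly.
#' @export
write_sensorgrams <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!"curve" %in% names(data)) data$curve <- match(data$conc, unique(data$conc))
  paths <- purrr::map_chr(unique(data$curve), function(cv) {
    d <- data[data$curve == cv, ]
    p <- file.path(dir, sprintf("curve_%02d.txt", cv))
    writeLines(c(sprintf("# conc_M: %.6g", d$conc[1]),
                 sprintf("%.6g\t%.6g", d$time, d$response)), p)
    p
  })
  invisible(paths)
}

#' Fetch structures from the RCSB PDB (explicit, never implicit)
#'
#' Downloads mmCIF files for the given accessions into a local directory.
#' The analysis pipeline itself only ever reads local files; this helper
#' is the one place that touches the network and requires internet
#' access.
#'
#' @param accessions PDB ids (e.g. `c("6SF3", "4FAO")`).
#' @param dir Destination directory.
#' @param quiet Suppress download progress.
#' @return Tibble with `accession`, `path`, `ok`.
#' @export
fetch_structures <- function(accessions, dir = "structures", quiet = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  purrr::map_dfr(accessions, function(acc) {
    path <- file.path(dir, paste0(tolower(acc), ".cif"))
    if (file.exists(path)) return(tibble(accession = acc, path = path, ok = TRUE))
    url <- paste0("https://files.rcsb.org/download/", toupper(acc), ".cif")
    ok <- tryCatch({
      utils::download.file(url, path, quiet = quiet, mode = "wb")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok && file.exists(path)) unlink(path)
    tibble(accession = acc, path = path, ok = ok)
  })
}

default_thresholds <- function() {
  list(min_delta = 0.1, hbond_max_dist = 3.5, hbond_min_angle = 90,
       saltbridge_max_dist = 4.0, family_min = 6,
       aug_min_required = 3, aug_max_disp = 2.0, sasa_n_points = 960)
}

validate_config <- function(config) {
  errs <- character(0)
  th <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  rng <- list(min_delta = c(0, 50), hbond_max_dist = c(2, 5),
              hbond_min_angle = c(0, 180), saltbridge_max_dist = c(2, 6),
              family_min = c(2, 50), aug_min_required = c(1, 50),
              aug_max_disp = c(0.1, 10), sasa_n_points = c(92, 1e6))
  for (nm in names(rng)) {
    v <- th[[nm]]
    if (!is.numeric(v) || v < rng[[nm]][1] || v > rng[[nm]][2])
      errs <- c(errs, paste0("threshold '", nm, "' out of range [",
                             rng[[nm]][1], ", ", rng[[nm]][2], "]"))
  }
  for (st in config$structures)
    if (!is.null(st$path) && !file.exists(st$path))
      errs <- c(errs, paste0("structure file missing: ", st$path))
  if (!is.null(config$alignment$path) && !file.exists(config$alignment$path))
    errs <- c(errs, paste0("alignment file missing: ", config$alignment$path))
  if (length(config$conservation) > 0 && is.null(config$alignment))
    errs <- c(errs, "conservation requested but 'alignment' is not configured")
  for (p in config$spr$files %||% character(0))
    if (!file.exists(p)) errs <- c(errs, paste0("sensorgram file missing: ", p))
  list(errors = errs, thresholds = th)
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(list(value = expr, error = NULL),
                  error = function(e) list(value = NULL,
                                           error = conditionMessage(e)))
  report$sections[[name]] <- res$value
  if (!is.null(res$error))
    report$errors <- c(report$errors, stats::setNames(res$error, name))
  report
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages run in dependency order (structures, then interfaces / contacts
#' / superpositions, then conservation, then specificity; SPR fitting is
#' independent). A failure in one branch is recorded and does not abort
#' independent branches. Re-running an unchanged configuration reproduces
#' the report exactly: every stochastic stage is seeded from
#' `config$seed`.
#'
#' @param config A list, or path to a YAML file. Recognised fields:
#'   `seed`; `thresholds` (any of `min_delta`, `hbond_max_dist`,
#'   `hbond_min_angle`, `saltbridge_max_dist`, `family_min`,
#'   `aug_min_required`, `aug_max_disp`, `sasa_n_points`); `structures`
#'   (named list: `path`, optional `orf_references` named list
#'   chain -> reference sequence); `interfaces` (list of `structure`,
#'   `group_a`, `group_b`); `contacts` (list of `structure`, `chains_a`,
#'   `chains_b`); `superpositions` (list of `moving`, `fixed`,
#'   `chains_moving`, `chains_fixed`); `alignment` (`path` or `rows`,
#'   `orf_starts`, `subfamily`); `spr` (`files` or `simulate` parameters,
#'   `t_assoc`, `model`).
#' @return An `analysis_report`: list with `sections` (per-stage
#'   results), `errors` (named character vector), `thresholds`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  val <- validate_config(config)
  if (length(val$errors) > 0)
    rlang::abort(paste0("invalid configuration:\n",
                        paste0("  - ", val$errors, collapse = "\n")))
  th <- val$thresholds
  seed <- config$seed %||% 1L
  report <- structure(list(sections = list(), errors = character(0),
                           thresholds = th,
                           provenance = list(seed = seed,
                                             timestamp = format(Sys.time()),
                                             version = as.character(
                                               utils::packageVersion("bmpspec")))),
                      class = "analysis_report")

  models <- list()
  for (nm in names(config$structures)) {
    st <- config$structures[[nm]]
    report <- run_stage(report, paste0("structure_", nm), {
      m <- read_structure(st$path, id = nm)
      for (ch in names(st$orf_references %||% list()))
        m <- assign_orf(m, ch, st$orf_references[[ch]])
      m
    })
    if (!is.null(report$sections[[paste0("structure_", nm)]]))
      models[[nm]] <- report$sections[[paste0("structure_", nm)]]
  }

  for (i in seq_along(config$interfaces)) {
    sp <- config$interfaces[[i]]
    report <- run_stage(report, paste0("interface_", i), {
      ir <- interface_report(models[[sp$structure]],
                             unlist(sp$group_a), unlist(sp$group_b),
                             min_delta = th$min_delta,
                             n_points = th$sasa_n_points)
      ir
    })
  }

  for (i in seq_along(config$contacts)) {
    sp <- config$contacts[[i]]
    report <- run_stage(report, paste0("contacts_", i), {
      hb <- find_hbonds(models[[sp$structure]], unlist(sp$chains_a),
                        unlist(sp$chains_b), max_dist = th$hbond_max_dist,
                        min_angle = th$hbond_min_angle)
      sb <- find_salt_bridges(models[[sp$structure]], unlist(sp$chains_a),
                              unlist(sp$chains_b),
                              max_dist = th$saltbridge_max_dist)
      list(hbonds = hb, salt_bridges = sb,
           ladders = group_sheet_ladders(hb))
    })
  }

  for (i in seq_along(config$superpositions)) {
    sp <- config$superpositions[[i]]
    report <- run_stage(report, paste0("superpose_", i), {
      s <- superpose_models(models[[sp$moving]], models[[sp$fixed]],
                            unlist(sp$chains_moving), unlist(sp$chains_fixed))
      tibble(moving = sp$moving, fixed = sp$fixed, rmsd = s$rmsd,
             n_atoms = s$n_atoms, coverage = s$correspondence$coverage,
             source = s$correspondence$source)
    })
  }

  if (!is.null(config$alignment)) {
    report <- run_stage(report, "conservation", {
      aln <- if (!is.null(config$alignment$path))
        read_alignment(config$alignment$path,
                       unlist(config$alignment$orf_starts))
      else build_alignment(unlist(config$alignment$rows),
                           unlist(config$alignment$orf_starts))
      prof <- classify_positions(aln, unlist(config$alignment$subfamily),
                                 family_min = th$family_min)
      list(alignment = aln, profile = prof,
           class_counts = table(prof$class))
    })
  }

  if (!is.null(config$spr)) {
    report <- run_stage(report, "spr", {
      sprc <- config$spr
      data <- if (!is.null(sprc$files)) read_sensorgrams(unlist(sprc$files))
      else {
        kp <- kinetic_params(sprc$simulate$ka, sprc$simulate$kd,
                             sprc$simulate$Rmax, sprc$simulate$kt %||% Inf)
        make_sensorgrams(kp, unlist(sprc$simulate$concentrations),
                         noise_sd = sprc$simulate$noise_sd %||% 0,
                         seed = seed,
                         times = seq(0, sprc$t_assoc * 2, by = 5),
                         t_assoc = sprc$t_assoc)$data
      }
      fit_sensorgrams(data, t_assoc = sprc$t_assoc,
                      model = sprc$model %||% "mass_transport",
                      seed = seed)
    })
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> ", length(x$sections), " sections",
      if (length(x$errors) > 0) paste0(", ", length(x$errors), " stage error(s)"),
      "\n", sep = "")
  for (nm in names(x$sections)) cat("  -", nm, "\n")
  if (length(x$errors) > 0)
    for (nm in names(x$errors)) cat("  !", nm, ":", x$errors[[nm]], "\n")
  invisible(x)
}

report_tables <- function(report) {
  secs <- report$sections
  out <- list()
  for (nm in names(secs)) {
    s <- secs[[nm]]
    out[[nm]] <-
      if (inherits(s, "interface_report")) s$residues
      else if (inherits(s, "kinetic_fit")) tidy(s)
      else if (inherits(s, "structure_model")) residue_table(s)
      else if (is.data.frame(s)) as_tibble(s)
      else if (is.list(s) && !is.null(s$hbonds)) s$hbonds
      else if (is.list(s) && !is.null(s$profile)) as_tibble(s$profile)
      else NULL
  }
  purrr::compact(out)
}

#' Render an analysis report to files
#'
#' @param report An [run_pipeline()] result.
#' @param dir Output directory.
#' @param format One of `"tsv_bundle"`, `"json"`, `"markdown"`.
#' @return The written file paths, invisibly.
#' @export
render_report <- function(report, dir,
                          format = c("tsv_bundle", "json", "markdown")) {
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- report_tables(report)
  paths <- character(0)
  if (format == "tsv_bundle") {
    for (nm in names(tabs)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(tabs[[nm]], p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      paths <- c(paths, p)
    }
  } else if (format == "json") {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(
      list(provenance = report$provenance, thresholds = report$thresholds,
           errors = as.list(report$errors), tables = tabs),
      p, auto_unbox = TRUE, digits = NA, na = "null")
    paths <- p
  } else {
    p <- file.path(dir, "report.md")
    lines <- c("# Analysis report", "",
               paste0("- seed: ", report$provenance$seed),
               paste0("- version: ", report$provenance$version), "",
               "## Thresholds", "",
               paste0("- ", names(report$thresholds), ": ",
                      unlist(report$thresholds)), "")
    for (nm in names(tabs)) {
      tb <- utils::head(tabs[[nm]], 50)
      lines <- c(lines, paste0("## ", nm), "",
                 paste(names(tb), collapse = " | "),
                 paste(rep("---", ncol(tb)), collapse = " | "),
                 apply(tb, 1, paste, collapse = " | "), "")
    }
    writeLines(lines, p)
    paths <- p
  }
  invisible(paths)
}
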