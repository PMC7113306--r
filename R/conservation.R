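#' Read a gapped FASTA family alignment
#'
#' The alignment itself is an input (e.g. built with Clustal Omega or
#' MAFFT); this package classifies its columns, it does not align. Each
#' row's first residue is assigned a declared ORF start so every non-gap
#' cell maps to an open-reading-frame position in that protein.
#'
#' @param path Aligned FASTA (gap character `-`).
#' @param orf_starts Named integer vector: ORF number of each row's first
#'   (non-gap) residue. Rows absent from the vector start at 1.
#' @return A `family_alignment`: list with `mat` (rows x columns character
#'   matrix), `n_rows`, `n_cols`, `orf_starts`, and `orf_map` — a tibble
#'   `(row, column, residue, orf)` for all non-gap cells.
#' @export
read_alignment <- function(path, orf_starts = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  build_alignment(stats::setNames(as.character(seqs), names(seqs)), orf_starts)
}

build_alignment <- function(seqs, orf_starts = NULL) {
  if (length(seqs) < 2) rlang::abort("alignment needs at least 2 rows")
  if (length(unique(nchar(seqs))) != 1)
    rlang::abort("ragged alignment: rows have different lengths")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    rlang::abort("all alignment rows must be named")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  ok <- c(Biostrings::AA_STANDARD, "X", "U", "O", "-")
  if (!all(mat %in% ok))
    rlang::abort(paste0("non-amino characters in alignment: ",
                        paste(unique(mat[!(mat %in% ok)]), collapse = ", ")))
  starts <- stats::setNames(rep(1L, nrow(mat)), rownames(mat))
  if (!is.null(orf_starts)) starts[names(orf_starts)] <- as.integer(orf_starts)
  orf_map <- purrr::map_dfr(rownames(mat), function(rn) {
    nongap <- which(mat[rn, ] != "-")
    tibble(row = rn, column = nongap, residue = mat[rn, nongap],
           orf = starts[[rn]] + seq_along(nongap) - 1L)
  })
  structure(list(mat = mat, n_rows = nrow(mat), n_cols = ncol(mat),
                 orf_starts = starts, orf_map = orf_map),
            class = "family_alignment")
}

#' @export
print.family_alignment <- function(x, ...) {
  cat("<family_alignment> ", x$n_rows, " rows x ", x$n_cols, " columns\n",
      "  rows: ", paste(rownames(x$mat), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Tripartite conservation classification of alignment columns
#'
#' Each column is assigned exactly one class. Columns with a gap in any
#' subfamily row are `gap_in_subfamily`. Otherwise, if the modal residue
#' over all rows (gaps never count as matches) occurs at least
#' `family_min` times the column is `family_conserved`; else if all
#' subfamily cells are identical the column is `subfamily_conserved`
#' (residues preferentially conserved within the subfamily); else
#' `variable`.
#'
#' @param aln A `family_alignment`.
#' @param subfamily Row names of the subfamily (>= 2, e.g. BMP9 and BMP10).
#' @param family_min Identity count for family-level conservation
#'   (default 6, i.e. at least 6 of 7 aligned family members).
#' @param similarity_groups Optional list of character vectors; residues
#'   within a group are treated as identical (off by default — strict
#'   identity, matching asterisk-style conservation marking).
#' @return A `conservation_profile`: tibble with `column`, `class`,
#'   `modal_residue`, `modal_count`, `subfamily_residue`, plus attributes
#'   `subfamily`, `family_min`.
#' @export
classify_positions <- function(aln, subfamily, family_min = 6,
                               similarity_groups = NULL) {
  stopifnot(inherits(aln, "family_alignment"))
  if (!all(subfamily %in% rownames(aln$mat)))
    rlang::abort("subfamily rows not all present in alignment")
  if (length(subfamily) < 2) rlang::abort("subfamily needs >= 2 rows")
  if (family_min > aln$n_rows)
    rlang::abort("family_min exceeds the number of alignment rows")

  canon <- function(res) {
    if (is.null(similarity_groups)) return(res)
    for (g in similarity_groups) res[res %in% g] <- g[1]
    res
  }
  out <- purrr::map_dfr(seq_len(aln$n_cols), function(j) {
    cells <- aln$mat[, j]
    sub_cells <- cells[subfamily]
    nongap <- canon(cells[cells != "-"])
    counts <- if (length(nongap) > 0) sort(table(nongap), decreasing = TRUE)
      else table(character(0))
    modal <- if (length(counts) > 0) names(counts)[1] else NA_character_
    modal_n <- if (length(counts) > 0) as.integer(counts[1]) else 0L
    cls <- if (any(sub_cells == "-")) "gap_in_subfamily"
      else if (modal_n >= family_min) "family_conserved"
      else if (length(unique(canon(sub_cells))) == 1) "subfamily_conserved"
      else "variable"
    tibble(column = j, class = cls, modal_residue = modal,
           modal_count = modal_n,
           subfamily_residue = if (length(unique(sub_cells)) == 1)
             sub_cells[1] else NA_character_)
  })
  structure(out, class = c("conservation_profile", class(out)),
            subfamily = subfamily, family_min = family_min)
}

#' Map a conservation profile onto structure residues
#'
#' Carries per-column classes through one alignment row's ORF offsets onto
#' the residues of a model chain. Residues present in the profile but not
#' modelled in the structure are flagged, not dropped.
#'
#' @param profile A [classify_positions()] result.
#' @param aln The `family_alignment` the profile came from.
#' @param row Alignment row to project through (e.g. `"BMP10"`).
#' @param model A `structure_model` with ORF numbering assigned
#'   ([assign_orf()]).
#' @param chain_id Chain of `model` corresponding to `row`.
#' @return Tibble with `orf`, `residue` (alignment), `class`, `modelled`,
#'   `chain`, `resno`, `resid1` (structure), one row per non-gap alignment
#'   cell of `row`.
#' @export
map_profile_to_structure <- function(profile, aln, row, model, chain_id) {
  stopifnot(inherits(aln, "family_alignment"))
  rowmap <- filter(aln$orf_map, .data$row == !!row)
  if (nrow(rowmap) == 0) rlang::abort(paste0("row '", row, "' not in alignment"))
  res <- residue_table(model) |> filter(.data$chain == chain_id)
  rowmap |>
    left_join(as_tibble(profile)[, c("column", "class")], by = "column") |>
    left_join(res |> select("chain", "resno", "orf", struct_res = "resid1"),
              by = "orf") |>
    mutate(modelled = !is.na(.data$resno)) |>
    select("orf", "residue", "class", "modelled", "chain", "resno",
           "struct_res")
}

#' Partition an interface residue set by conservation class
#'
#' Splits interface residues into the tripartite sets: family-conserved
#' core, subfamily-specific, and variable. Residues listed in `overrides`
#' are promoted into the subfamily-specific set with an explicit
#' `override` tag and justification — the channel for residues that vary
#' in sequence but make conserved interactions across complexes — never
#' silently merged.
#'
#' @param interface_orf Integer vector of interface residue ORF numbers.
#' @param class_table A [map_profile_to_structure()] result covering the
#'   interface.
#' @param overrides Optional named character vector: names are ORF
#'   numbers to promote, values the justification tag.
#' @return Tibble with `orf`, `residue`, `class`, `partition`
#'   (`core_conserved` / `subfamily_specific` / `variable`), `override`,
#'   `justification`.
#' @export
tripartite_partition <- function(interface_orf, class_table, overrides = NULL) {
  miss <- setdiff(interface_orf, class_table$orf)
  if (length(miss) > 0)
    rlang::abort(paste0("interface residues not covered by class table: ",
                        paste(miss, collapse = ", ")))
  tb <- class_table |>
    filter(.data$orf %in% interface_orf) |>
    mutate(
      partition = dplyr::case_when(
        class == "family_conserved" ~ "core_conserved",
        class == "subfamily_conserved" ~ "subfamily_specific",
        TRUE ~ "variable"
      ),
      override = FALSE, justification = NA_character_
    )
  if (!is.null(overrides)) {
    pos <- as.integer(names(overrides))
    hit <- tb$orf %in% pos
    tb$partition[hit & tb$partition == "variable"] <- "subfamily_specific"
    tb$override[hit] <- TRUE
    tb$justification[hit] <- overrides[as.character(tb$orf[hit])]
  }
  select(tb, "orf", "residue", "class", "partition", "override",
         "justification")
}

#' Tile plot of a conservation profile
#' @param object A [classify_positions()] result.
#' @param ... Unused.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$column, y = 1, fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      family_conserved = "firebrick", subfamily_conserved = "steelblue",
      variable = "goldenrod", gap_in_subfamily = "grey80")) +
    ggplot2::labs(x = "alignment column", y = NULL,
                  title = "Tripartite conservation classes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
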