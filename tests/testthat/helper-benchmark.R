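# Helpers for the deposited-structure benchmarks. The coordinate files are
# not distributable with the package; a one-time
#   fetch_structures(c("6SF3","6SF2","4FAO","4YCG","3BK3","5HZW"),
#                    dir = testthat::test_path("structures"))
# run (network required) places them where these helpers look.

benchmark_paths <- function(accs = c("6sf3", "6sf2", "4fao", "4ycg",
                                     "3bk3", "5hzw")) {
  stats::setNames(file.path(testthat::test_path("structures"),
                            paste0(accs, ".cif")), accs)
}

seq_identity <- function(s1, s2) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2), type = "overlap",
    substitutionMatrix = bmpspec:::identity_submat(), gapOpening = 10,
    gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ok <- pat != "-" & sub != "-"
  if (!any(ok)) return(0)
  sum(pat[ok] == sub[ok]) / min(nchar(s1), nchar(s2))
}

chain_seqs <- function(model) {
  chains <- unique(model$atoms$chain[model$atoms$is_polymer])
  stats::setNames(vapply(chains, function(ch)
    paste(bmpspec:::chain_sequence(model, ch)$resid1, collapse = ""),
    character(1)), chains)
}

# group a model's chains into molecule types by observed-sequence identity
chain_types <- function(model, min_identity = 0.9) {
  seqs <- chain_seqs(model)
  groups <- list()
  for (ch in names(seqs)) {
    placed <- FALSE
    for (i in seq_along(groups)) {
      if (seq_identity(seqs[[ch]], seqs[[groups[[i]][1]]]) >= min_identity) {
        groups[[i]] <- c(groups[[i]], ch); placed <- TRUE; break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- ch
  }
  groups
}

# which type matches a reference sequence best
match_type <- function(model, types, ref_seq) {
  seqs <- chain_seqs(model)
  idents <- vapply(types, function(g) seq_identity(seqs[[g[1]]], ref_seq),
                   numeric(1))
  types[[which.max(idents)]]
}

# among two-chain types, the ligand dimer is the pair burying the largest
# intra-pair surface (receptor copies are not in mutual contact)
dimer_type <- function(model, types) {
  pairs <- types[lengths(types) == 2]
  bsa <- vapply(pairs, function(g)
    interface_report(model, g[1], g[2], n_points = 240)$bsa_total, numeric(1))
  pairs[[which.max(bsa)]]
}

# minimum RMSD over the copy-assignment ambiguity of a symmetric assembly
min_rmsd <- function(model_a, model_b, chains_a, chains_b_orderings) {
  min(vapply(chains_b_orderings, function(cb)
    superpose_models(model_a, model_b, chains_a, cb)$rmsd, numeric(1)))
}

# the largest backbone ladder between two chain groups
largest_ladder <- function(model, chains_a, chains_b) {
  hb <- find_hbonds(model, chains_a, chains_b, mainchain_only = TRUE)
  lads <- group_sheet_ladders(hb)
  if (length(lads) == 0) return(NULL)
  lads[[which.max(vapply(lads, function(l) nrow(l$hbonds), numeric(1)))]]
}
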