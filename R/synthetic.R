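#' Specification for a synthetic proteome
#'
#' Describes an i.i.d.-residue proteome with controlled per-amino-acid HPAA
#' tract insertion. Peptide lengths are uniform on `len_range`; residues are
#' drawn independently from `residue_freq` (default: the JTT stationary
#' frequencies, a realistic average amino-acid composition). For each amino
#' acid `a` with insertion probability `tract_prob[a] > 0`, a peptide
#' receives (with that probability) one homopolymer tract of `a` whose
#' length is `min_tract_len` plus a geometric excess, spliced in at a
#' uniform position.
#'
#' @param n_peptides Number of peptides.
#' @param len_range Length range `c(min, max)` (uniform).
#' @param residue_freq Named numeric vector of 20 residue frequencies
#'   (summing to 1).
#' @param tract_prob Named numeric vector of per-amino-acid tract insertion
#'   probabilities (absent letters mean 0).
#' @param min_tract_len Minimum inserted tract length (default 6).
#' @param tract_geom_p Geometric parameter for the tract-length excess
#'   (default 0.3).
#' @param species Species tag for the generated peptides.
#' @return List of class `proteome_spec`.
#' @export
proteome_spec <- function(n_peptides = 1000, len_range = c(100, 600),
                          residue_freq = NULL, tract_prob = numeric(0),
                          min_tract_len = 6, tract_geom_p = 0.3,
                          species = "synthetic") {
  if (is.null(residue_freq)) {
    residue_freq <- setNames(.jtt_freq, .aa_order)
  }
  stopifnot(abs(sum(residue_freq) - 1) < 1e-6,
            all(residue_freq >= 0),
            all(tract_prob >= 0), all(tract_prob <= 1),
            min_tract_len >= 2, tract_geom_p > 0, tract_geom_p <= 1)
  if (length(tract_prob) && is.null(names(tract_prob))) {
    stop("tract_prob must be named by amino acid")
  }
  structure(list(n_peptides = n_peptides, len_range = len_range,
                 residue_freq = residue_freq, tract_prob = tract_prob,
                 min_tract_len = min_tract_len, tract_geom_p = tract_geom_p,
                 species = species),
            class = "proteome_spec")
}

#' Generate a synthetic proteome with known tract truth
#'
#' Draws peptides according to a [proteome_spec()] and returns both the
#' peptide table and a truth table listing every inserted tract (peptide,
#' amino acid, position after insertion, length). Deterministic for a fixed
#' seed.
#'
#' @param spec A [proteome_spec()].
#' @param seed Integer seed (required).
#' @return List with `peptides` (sequence table) and `truth`
#'   (`data.frame` of inserted tracts).
#' @export
generate_proteome <- function(spec, seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  n <- spec$n_peptides
  lens <- spec$len_range[1] +
    sample.int(spec$len_range[2] - spec$len_range[1] + 1L, n,
               replace = TRUE) - 1L
  seqs <- character(n)
  truth <- list()
  aa_with_p <- names(spec$tract_prob)[spec$tract_prob > 0]
  for (i in seq_len(n)) {
    s <- paste(sample(.aa_order, lens[i], replace = TRUE,
                      prob = spec$residue_freq), collapse = "")
    # draw all insertion points in original coordinates first, then
    # assemble, so no tract can ever split another
    ins <- list()
    for (a in aa_with_p) {
      if (runif(1) < spec$tract_prob[a]) {
        tl <- spec$min_tract_len + rgeom(1, spec$tract_geom_p)
        if (tl > nchar(s)) stop("tract longer than peptide; adjust spec")
        ins[[length(ins) + 1L]] <-
          list(aa = a, len = tl, pos = sample.int(nchar(s) + 1L, 1L))
      }
    }
    if (length(ins)) {
      o <- order(vapply(ins, `[[`, 0L, "pos"))
      parts <- character(0)
      cur <- 1L; shift <- 0L
      for (k in o) {
        e <- ins[[k]]
        parts <- c(parts, substr(s, cur, e$pos - 1L), strrep(e$aa, e$len))
        truth[[length(truth) + 1L]] <-
          data.frame(peptide_id = sprintf("pep%05d", i),
                     amino_acid = e$aa, start = e$pos + shift,
                     length = e$len, stringsAsFactors = FALSE)
        shift <- shift + e$len
        cur <- e$pos
      }
      parts <- c(parts, substring(s, cur))
      s <- paste(parts, collapse = "")
    }
    seqs[i] <- s
  }
  peptides <- data.frame(id = sprintf("pep%05d", seq_len(n)),
                         species = spec$species, gene_id = NA_character_,
                         sequence = seqs, stringsAsFactors = FALSE)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(peptide_id = character(), amino_acid = character(),
               start = integer(), length = integer(),
               stringsAsFactors = FALSE)
  list(peptides = peptides, truth = truth)
}

#' Expected number of chance runs in an i.i.d. sequence
#'
#' For a residue with frequency `q` in an i.i.d. sequence of length `n`,
#' the expected number of maximal runs of length at least `L` is
#' `q^L * (1 + (n - L) * (1 - q))` (a run can start at the first position,
#' or after a non-matching residue at any of the `n - L` later start
#' positions).
#'
#' @param n Sequence length.
#' @param q Residue frequency.
#' @param L Minimum run length.
#' @return Expected count (numeric).
#' @export
expected_chance_runs <- function(n, q, L) {
  if (n < L) return(0)
  q^L * (1 + (n - L) * (1 - q))
}

#' Simulate protein evolution along a tree
#'
#' Sites evolve independently down a rooted tree with branch lengths under
#' the model: the root is drawn from the stationary frequencies and each
#' site carries a rate drawn from the model's discrete-gamma categories
#' (plus an invariant class when `p_inv > 0`). No indels are produced.
#' Simulation of each rate class is delegated to \pkg{phangorn}'s sequence
#' simulator.
#'
#' @param tree Rooted `ape::phylo` with non-negative branch lengths.
#' @param model An [substitution_model()] object.
#' @param length Number of sites (>= 1).
#' @param seed Integer seed (required).
#' @return Character matrix (leaves x sites) of class `aa_alignment`.
#' @export
simulate_protein_evolution <- function(tree, model, length, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(length >= 1)
  if (any(tree$edge.length < 0)) stop("negative branch length")
  set.seed(seed)
  rates <- model$rates
  weights <- rep(1 / model$k, model$k)
  if (model$p_inv > 0) {
    rates <- c(0, rates / (1 - model$p_inv))
    weights <- c(model$p_inv, (1 - model$p_inv) * weights)
  }
  ncat <- as.vector(rmultinom(1, length, weights))
  blocks <- list()
  for (ci in seq_along(rates)) {
    if (ncat[ci] == 0) next
    if (rates[ci] == 0) {
      aa <- sample(.aa_order, ncat[ci], replace = TRUE, prob = model$freq)
      blk <- matrix(rep(aa, each = length(tree$tip.label)),
                    nrow = length(tree$tip.label),
                    dimnames = list(tree$tip.label, NULL))
    } else {
      sim <- phangorn::simSeq(tree, l = ncat[ci], type = "AA",
                              model = "JTT", bf = model$freq,
                              rate = rates[ci])
      blk <- toupper(as.character(sim))[tree$tip.label, , drop = FALSE]
    }
    blocks[[length(blocks) + 1L]] <- blk
  }
  m <- do.call(cbind, blocks)
  m <- m[, sample.int(ncol(m)), drop = FALSE] # shuffle category blocks
  as_alignment(m)
}

#' An HPAA injection instruction
#'
#' @param leaf Leaf label receiving the tract.
#' @param amino_acid Single residue letter.
#' @param length Tract length in residues.
#' @param position 1-based insertion point in the leaf's sequence.
#' @return One-row `data.frame`.
#' @export
hpaa_injection <- function(leaf, amino_acid, length, position) {
  stopifnot(amino_acid %in% .aa_order, length >= 1, position >= 1)
  data.frame(leaf = leaf, amino_acid = amino_acid, length = length,
             position = position, stringsAsFactors = FALSE)
}

#' Specification of a gene-family duplication-timing scenario
#'
#' Describes a six-gene family — three gnathostome paralogs (`g1`, `g2`,
#' `g3`), two cyclostome paralogs (`cA`, `cB`) and one outgroup leaf
#' (`out`) — whose true history places the duplications either on the stem
#' lineage before the cyclostome-gnathostome split (`"before_split"`: two
#' stem duplications, the third cyclostome copy lost) or independently
#' within each lineage (`"independent"`: two gnathostome and one cyclostome
#' duplication). Node heights (substitutions/site): the split at
#' `depths["split"]`, duplications at `depths["dup1"] > depths["dup2"]`
#' (stem mode) or within-lineage heights below the split (independent
#' mode), outgroup attachment at `depths["root"]`.
#'
#' @param scenario `"before_split"` or `"independent"`.
#' @param n_sites Sequence length simulated (default 300).
#' @param alpha Gamma shape for rate heterogeneity (default 0.5).
#' @param depths Named numeric vector of node heights; defaults give
#'   internal branches of at least 0.05 substitutions/site.
#' @param injections `data.frame` of [hpaa_injection()] rows applied to the
#'   leaf sequences after simulation (`NULL` for none).
#' @return List of class `scenario_spec`, including the true gene tree.
#' @export
scenario_spec <- function(scenario = c("before_split", "independent"),
                          n_sites = 300, alpha = 0.5, depths = NULL,
                          injections = NULL) {
  scenario <- match.arg(scenario)
  depths <- depths %||% c(root = 0.8, dup1 = 0.6, dup2 = 0.5, split = 0.4)
  if (scenario == "before_split") {
    stopifnot(depths["root"] > depths["dup1"],
              depths["dup1"] > depths["dup2"],
              depths["dup2"] > depths["split"], depths["split"] > 0)
    d <- depths
    nwk <- sprintf(
      "(out:%g,((g1:%g,cA:%g):%g,((g2:%g,cB:%g):%g,g3:%g):%g):%g);",
      d["root"], d["split"], d["split"], d["dup1"] - d["split"],
      d["split"], d["split"], d["dup2"] - d["split"], d["dup2"],
      d["dup1"] - d["dup2"], d["root"] - d["dup1"])
  } else {
    d <- c(depths,
           gdup1 = unname(depths["split"]) * 0.75,
           gdup2 = unname(depths["split"]) * 0.5,
           cdup = unname(depths["split"]) * 0.625)
    nwk <- sprintf(
      "(out:%g,(((g1:%g,g2:%g):%g,g3:%g):%g,(cA:%g,cB:%g):%g):%g);",
      d["root"], d["gdup2"], d["gdup2"], d["gdup1"] - d["gdup2"],
      d["gdup1"], d["split"] - d["gdup1"], d["cdup"], d["cdup"],
      d["split"] - d["cdup"], d["root"] - d["split"])
  }
  tree <- ape::read.tree(text = nwk)
  if (!is.null(injections)) {
    stopifnot(all(injections$leaf %in% tree$tip.label),
              all(injections$position <= n_sites + 1L))
  }
  structure(list(scenario = scenario, n_sites = n_sites, alpha = alpha,
                 depths = depths, tree = tree, injections = injections),
            class = "scenario_spec")
}

#' Realize a duplication-timing scenario
#'
#' Simulates sequences on the scenario's true gene tree under JTT with
#' discrete-gamma rates, applies any HPAA injections (in-place insertion
#' into the designated leaves, mimicking tract expansion by replication
#' slippage), and returns the data with its ground truth.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed (required).
#' @return List with `sequences` (named character vector, unaligned),
#'   `tree` (true gene tree), `assignment` (leaf group map), `truth`
#'   (named duplication counts of the true history), and `injected`
#'   (the injection table, possibly `NULL`).
#' @export
make_scenario <- function(spec, seed) {
  if (missing(seed)) stop("a seed is required")
  model <- substitution_model("JTT", alpha = spec$alpha, k = 4)
  aln <- simulate_protein_evolution(spec$tree, model, spec$n_sites, seed)
  seqs <- alignment_strings(aln)
  if (!is.null(spec$injections)) {
    for (i in seq_len(nrow(spec$injections))) {
      inj <- spec$injections[i, ]
      s <- seqs[inj$leaf]
      pos <- min(inj$position, nchar(s) + 1L)
      seqs[inj$leaf] <- paste0(substr(s, 1, pos - 1L),
                               strrep(inj$amino_acid, inj$length),
                               substring(s, pos))
    }
  }
  assignment <- species_assignment(
    c("g1", "g2", "g3", "cA", "cB", "out"),
    c("gnathostome", "gnathostome", "gnathostome",
      "cyclostome", "cyclostome", "outgroup"))
  ing <- root_on_outgroup(spec$tree, assignment)
  truth <- reconcile_count(ing, assignment)
  list(sequences = seqs, tree = spec$tree, assignment = assignment,
       truth = truth, injected = spec$injections)
}
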