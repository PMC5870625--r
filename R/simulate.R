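# Synthetic phosphoproteomic studies with embedded ground truth: Gaussian
# background fold changes, additive regulon shifts for regulated kinases,
# motif-consistent flanking sequences, and a matching gold standard.

#' Simulation configuration
#'
#' Defines a synthetic phosphoproteomic study. Defaults describe the
#' reference testbed used throughout the package: 2000 sites, 20 kinases
#' with regulons of 10-30 sites, 10 conditions with 2 regulated kinases
#' each, an additive log2 fold-change shift of 2 against unit Gaussian
#' background noise, 20% missing values, and substrate flanks matching the
#' kinase consensus at 90% of positions.
#'
#' @param n_sites number of phosphosites (each on its own 15-residue
#'   synthetic protein, phosphoacceptor at position 8)
#' @param n_kinases number of kinases
#' @param regulon_size_range integer `(min, max)` substrates per kinase
#' @param n_conditions number of perturbation conditions
#' @param regulated_per_condition kinases regulated in each condition
#' @param effect_size mean log2FC shift (delta) of regulated regulons
#' @param noise_sd background standard deviation (sigma)
#' @param missing_rate completely-at-random missingness in `[0, 1)`
#' @param regulon_overlap fraction of substrates shared within consecutive
#'   kinase pairs, in `[0, 1]`
#' @param motif_strength probability a substrate flank letter matches the
#'   kinase consensus (else uniform over 20 amino acids)
#' @param direction_mix fraction of regulated kinase-condition pairs that
#'   are down-regulated
#' @param scale_by_mss scale each substrate's true shift by its matrix
#'   similarity score (used when testing specificity weighting)
#' @param seed integer seed; the whole dataset is deterministic given it
#' @return object of class `sim_config`
#' @export
simulation_config <- function(n_sites = 2000, n_kinases = 20,
                              regulon_size_range = c(10, 30),
                              n_conditions = 10, regulated_per_condition = 2,
                              effect_size = 2, noise_sd = 1,
                              missing_rate = 0.2, regulon_overlap = 0,
                              motif_strength = 0.9, direction_mix = 0.5,
                              scale_by_mss = FALSE, seed = 1) {
  cfg <- list(
    n_sites = as.integer(n_sites), n_kinases = as.integer(n_kinases),
    regulon_size_range = as.integer(regulon_size_range),
    n_conditions = as.integer(n_conditions),
    regulated_per_condition = as.integer(regulated_per_condition),
    effect_size = effect_size, noise_sd = noise_sd,
    missing_rate = missing_rate, regulon_overlap = regulon_overlap,
    motif_strength = motif_strength, direction_mix = direction_mix,
    scale_by_mss = isTRUE(scale_by_mss), seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_sites >= 1, n_kinases >= 1, n_conditions >= 1,
      length(regulon_size_range) == 2,
      regulon_size_range[1] >= 1,
      regulon_size_range[2] >= regulon_size_range[1],
      regulated_per_condition <= n_kinases,
      effect_size >= 0, noise_sd > 0,
      missing_rate >= 0, missing_rate < 1,
      regulon_overlap >= 0, regulon_overlap <= 1,
      motif_strength >= 0, motif_strength <= 1,
      direction_mix >= 0, direction_mix <= 1
    )
  })
  if (cfg$regulon_size_range[2] > cfg$n_sites) {
    stop("regulon_size_range max exceeds n_sites", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# draw one window: each position from the consensus with prob `strength`,
# otherwise uniform over the 20 amino acids; the center stays a
# phosphoacceptor (consensus center with prob `strength`, else uniform STY)
draw_window <- function(consensus, strength) {
  letters20 <- AA20
  cons <- strsplit(consensus, "")[[1]]
  take <- runif(WINDOW) < strength
  win <- ifelse(take, cons, sample(letters20, WINDOW, replace = TRUE))
  center <- (WINDOW + 1L) / 2L
  if (!take[center]) win[center] <- sample(c("S", "T", "Y"), 1)
  paste(win, collapse = "")
}

#' Generate motif-consistent protein sequences for a network
#'
#' Assigns every kinase a random 15-letter consensus (phosphoacceptor at the
#' center) and draws each substrate site's protein sequence letter-wise from
#' that consensus with probability `motif_strength`, else uniformly over the
#' 20 amino acids. Sites in `sites` that are not substrates of any kinase
#' get uniform sequences with the recorded phosphoacceptor at the center.
#' A site claimed by several kinases follows the first kinase's motif.
#'
#' @param sites data.frame `(protein, position, residue)`; positions must be
#'   8 (center of the 15-residue synthetic proteins)
#' @param network a [ks_network()]
#' @param motif_strength consensus-match probability in `[0, 1]`
#' @param seed optional integer seed
#' @return list with `sequences` (named character, one 15-mer per protein),
#'   `consensus` (named character, one 15-mer per kinase), and `residues`
#'   (possibly updated site residues, matching the sequence centers)
#' @export
simulate_sequences <- function(sites, network, motif_strength, seed = NULL) {
  stopifnot(all(sites$position == (WINDOW + 1L) / 2L))
  maybe_set_seed(seed)
  kinases <- unique(network$kinase)
  center <- (WINDOW + 1L) / 2L
  consensus <- vapply(kinases, function(k) {
    cons <- sample(AA20, WINDOW, replace = TRUE)
    cons[center] <- sample(c("S", "T", "Y"), 1)
    paste(cons, collapse = "")
  }, character(1))
  owner <- rep(NA_character_, nrow(sites))
  skey <- match_key(sites$protein, sites$position)
  for (k in kinases) {
    ks <- match_key(network$protein[network$kinase == k],
                    network$position[network$kinase == k])
    hit <- is.na(owner) & skey %in% ks
    owner[hit] <- k
  }
  seqs <- vapply(seq_len(nrow(sites)), function(i) {
    if (is.na(owner[i])) {
      win <- sample(AA20, WINDOW, replace = TRUE)
      win[center] <- sites$residue[i]
      paste(win, collapse = "")
    } else {
      draw_window(consensus[[owner[i]]], motif_strength)
    }
  }, character(1))
  names(seqs) <- sites$protein
  list(
    sequences = seqs,
    consensus = consensus,
    residues = substr(seqs, center, center)
  )
}

#' Simulate a complete synthetic phosphoproteomic study
#'
#' Background log2 fold changes are i.i.d. `Normal(0, noise_sd^2)`. In each
#' condition, `regulated_per_condition` kinases receive an additive shift of
#' `+/- effect_size` on their substrate sites (sign per the drawn direction;
#' optionally scaled per site by the site's true MSS under the generating
#' PWM when `scale_by_mss` is set). Entries are then masked missing
#' completely at random. The returned gold standard lists exactly the
#' (kinase, condition) pairs with a nonzero true shift.
#'
#' @param config a [simulation_config()]
#' @return object of class `synthetic_phospho`: list with `quant`
#'   (a [site_quant()], already on a common scale so marked normalized),
#'   `network` (a [ks_network()]), `sequences` (named character),
#'   `consensus` (per-kinase generating motifs), `gold`
#'   (`kinase, condition, direction`), `truth`
#'   (`kinase, condition, shift`), and `config`
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  proteins <- sprintf("SIMP%05d", seq_len(cfg$n_sites))
  center <- (WINDOW + 1L) / 2L
  sites <- data.frame(
    protein = proteins,
    position = center,
    residue = sample(c("S", "T", "Y"), cfg$n_sites, replace = TRUE,
                     prob = c(0.6, 0.25, 0.15)),
    stringsAsFactors = FALSE
  )

  kinases <- sprintf("KIN%02d", seq_len(cfg$n_kinases))
  size_choices <- seq.int(cfg$regulon_size_range[1], cfg$regulon_size_range[2])
  sizes <- size_choices[sample.int(length(size_choices), cfg$n_kinases,
                                   replace = TRUE)]
  reg_idx <- vector("list", cfg$n_kinases)
  for (i in seq_len(cfg$n_kinases)) {
    if (cfg$regulon_overlap > 0 && i %% 2L == 0L) {
      # consecutive pairs (1,2), (3,4), ... share a fraction of substrates
      prev <- reg_idx[[i - 1L]]
      n_shared <- min(round(cfg$regulon_overlap * sizes[i]), length(prev))
      shared <- if (n_shared > 0) prev[sample.int(length(prev), n_shared)] else integer()
      fresh <- sample(setdiff(seq_len(cfg$n_sites), shared),
                      sizes[i] - n_shared)
      reg_idx[[i]] <- c(shared, fresh)
    } else {
      reg_idx[[i]] <- sample.int(cfg$n_sites, sizes[i])
    }
  }
  network <- ks_network(data.frame(
    kinase = rep(kinases, sizes),
    protein = sites$protein[unlist(reg_idx)],
    position = center,
    residue = sites$residue[unlist(reg_idx)],
    evidence = "in_vivo",
    stringsAsFactors = FALSE
  ))

  sq <- simulate_sequences(sites, network, cfg$motif_strength,
                           seed = child_seed(cfg$seed, 1L))
  sites$residue <- sq$residues
  network$residue <- sites$residue[match(network$protein, sites$protein)]

  site_mss <- rep(1, cfg$n_sites)
  if (cfg$scale_by_mss) {
    # true per-site MSS under the generating motif's empirical PWM
    pwms <- build_pwm_library(network, sq$sequences, min_substrates = 1)
    mt <- mss_table(network, pwms, sq$sequences)
    mt <- mt[!duplicated(mt$site), , drop = FALSE]
    idx <- match(match_key(sites$protein, sites$position), mt$site)
    site_mss[!is.na(idx)] <- mt$mss[idx[!is.na(idx)]]
  }

  conditions <- sprintf("cond%02d", seq_len(cfg$n_conditions))
  values <- matrix(
    rnorm(cfg$n_sites * cfg$n_conditions, 0, cfg$noise_sd),
    cfg$n_sites, cfg$n_conditions,
    dimnames = list(site_key(sites$protein, sites$position, sites$residue),
                    conditions)
  )
  truth <- data.frame(kinase = character(), condition = character(),
                      shift = numeric(), stringsAsFactors = FALSE)
  if (cfg$effect_size > 0) {
    for (j in seq_len(cfg$n_conditions)) {
      reg_kin <- sample.int(cfg$n_kinases, cfg$regulated_per_condition)
      for (ki in reg_kin) {
        down <- runif(1) < cfg$direction_mix
        shift <- if (down) -cfg$effect_size else cfg$effect_size
        rows <- reg_idx[[ki]]
        values[rows, j] <- values[rows, j] + shift * site_mss[rows]
        truth <- rbind(truth, data.frame(
          kinase = kinases[ki], condition = conditions[j], shift = shift,
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  if (cfg$missing_rate > 0) {
    values[runif(length(values)) < cfg$missing_rate] <- NA_real_
  }
  gold <- if (nrow(truth)) data.frame(
    kinase = truth$kinase, condition = truth$condition,
    direction = ifelse(truth$shift > 0, "up", "down"),
    stringsAsFactors = FALSE
  ) else data.frame(kinase = character(), condition = character(),
                    direction = character(), stringsAsFactors = FALSE)

  structure(
    list(quant = site_quant(values, sites = sites, normalized = TRUE),
         network = network, sequences = sq$sequences,
         consensus = sq$consensus, gold = gold, truth = truth,
         config = cfg),
    class = "synthetic_phospho"
  )
}

#' @export
print.synthetic_phospho <- function(x, ...) {
  cat("synthetic_phospho: ", nrow(x$quant$values), " sites x ",
      length(x$quant$conditions), " conditions, ",
      length(unique(x$network$kinase)), " kinases, ",
      nrow(x$gold), " gold pairs (effect ", x$config$effect_size,
      ", noise ", x$config$noise_sd, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `quant.tsv` (site-by-condition matrix), `network.tsv`,
#' `sequences.fa`, `gold.tsv` and `truth.tsv`.
#'
#' @param dataset a `synthetic_phospho` from [simulate_dataset()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_phospho"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_quant_matrix(dataset$quant, file.path(dir, "quant.tsv"))
  utils::write.table(as.data.frame(dataset$network),
                     file.path(dir, "network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_protein_fasta(dataset$sequences, file.path(dir, "sequences.fa"))
  utils::write.table(dataset$gold, file.path(dir, "gold.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
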