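# Kinase sequence specificity: flanking windows, position weight matrices,
# and MATCH-style matrix similarity scores used to weight substrate fold
# changes as a proxy for binding affinity.

FLANK <- 7L
WINDOW <- 2L * FLANK + 1L

#' Read / write protein sequences in FASTA format
#'
#' Thin wrappers around `Biostrings`; sequences are handled in-package as a
#' named character vector. FASTA ids are truncated at the first whitespace.
#'
#' @param path FASTA file
#' @return named character vector of amino-acid sequences
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  stats::setNames(as.character(aa), names(aa))
}

#' @rdname read_protein_fasta
#' @param seqs named character vector of sequences
#' @export
write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Extract +/-7 residue flanking windows around phosphosites
#'
#' Returns the 15-character amino-acid window centered on each site, padded
#' with `_` where the window runs past a protein terminus. Sites on proteins
#' absent from the sequence set, or positioned beyond the sequence length,
#' are skipped with a warning. When the recorded phosphoacceptor disagrees
#' with the sequence letter at the site position, the sequence letter wins
#' (with a warning).
#'
#' @param sites data.frame with columns `protein`, `position`, `residue`
#' @param seqs protein sequences: a named character vector or a
#'   `Biostrings::AAStringSet`
#' @return data.frame `(protein, position, residue, window)`
#' @export
extract_flanks <- function(sites, seqs) {
  if (methods::is(seqs, "AAStringSet")) seqs <- as.character(seqs)
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  present <- sites$protein %in% names(seqs)
  if (any(!present)) {
    warning(sum(!present), " site(s) on proteins missing from the sequence set",
            call. = FALSE)
    sites <- sites[present, , drop = FALSE]
  }
  if (nrow(sites) == 0) {
    return(data.frame(protein = character(), position = integer(),
                      residue = character(), window = character(),
                      stringsAsFactors = FALSE))
  }
  seq_len_of <- nchar(seqs)[sites$protein]
  inside <- sites$position >= 1 & sites$position <= seq_len_of
  if (any(!inside)) {
    warning(sum(!inside), " site(s) positioned beyond their protein length; skipped",
            call. = FALSE)
    sites <- sites[inside, , drop = FALSE]
  }
  n_mismatch <- 0L
  out <- sites[, c("protein", "position", "residue")]
  out$window <- vapply(seq_len(nrow(sites)), function(i) {
    s <- seqs[[sites$protein[i]]]
    p <- sites$position[i]
    L <- nchar(s)
    from <- max(1L, p - FLANK); to <- min(L, p + FLANK)
    core <- substr(s, from, to)
    win <- paste0(
      strrep(PAD, from - (p - FLANK)), core, strrep(PAD, (p + FLANK) - to)
    )
    center <- substr(s, p, p)
    if (center != sites$residue[i]) n_mismatch <<- n_mismatch + 1L
    win
  }, character(1))
  if (n_mismatch > 0) {
    warning(n_mismatch, " site(s) whose recorded residue differs from the ",
            "sequence; sequence residue used", call. = FALSE)
    out$residue <- substr(out$window, FLANK + 1L, FLANK + 1L)
  }
  rownames(out) <- NULL
  out
}

#' Build a position weight matrix from substrate flanking windows
#'
#' Frequencies over the 20 amino acids plus the terminal padding symbol `_`
#' (alphabet size K = 21): `f(i, b) = (count(i, b) + pseudocount) /
#' (n + K * pseudocount)`. The per-position information vector is
#' `I(i) = sum_b f(i, b) * ln(K * f(i, b))`, the Kullback-Leibler divergence
#' from the uniform background; it reaches `ln(K)` only for single-letter
#' columns at pseudocount 0 and approaches 0 for uniform columns.
#'
#' @param windows character vector of 15-letter windows (or the data.frame
#'   from [extract_flanks()])
#' @param pseudocount added to every cell count (default 0.01; keeps the
#'   information vector finite for small regulons)
#' @param min_sequences minimum number of windows (default 10, the substrate
#'   count required for a usable specificity model)
#' @param kinase optional kinase id recorded in the model
#' @return object of class `kinase_pwm`: list with `kinase`, `f` (15 x 21
#'   row-stochastic matrix), `info` (length-15 information vector),
#'   `n_sequences`
#' @export
build_pwm <- function(windows, pseudocount = 0.01, min_sequences = 10,
                      kinase = NULL) {
  if (is.data.frame(windows)) windows <- windows$window
  n <- length(windows)
  if (n < min_sequences) {
    stop("insufficient substrate windows", if (!is.null(kinase))
      paste0(" for kinase ", kinase), ": ", n, " < ", min_sequences,
      call. = FALSE)
  }
  if (any(nchar(windows) != WINDOW)) {
    stop("all windows must have length ", WINDOW, call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(windows, ""))
  unknown <- !(mat %in% PWM_ALPHABET)
  if (any(unknown)) {
    warning(sum(unknown), " non-standard letter(s) treated as padding",
            call. = FALSE)
    mat[unknown] <- PAD
  }
  K <- length(PWM_ALPHABET)
  counts <- vapply(seq_len(WINDOW), function(i) {
    as.numeric(tabulate(factor(mat[, i], levels = PWM_ALPHABET), nbins = K))
  }, numeric(K))
  f <- t(counts + pseudocount) / (n + K * pseudocount)
  dimnames(f) <- list(NULL, PWM_ALPHABET)
  lf <- f * log(K * f)
  lf[f == 0] <- 0 # lim x->0 of x log x
  info <- rowSums(lf)
  structure(
    list(kinase = kinase, f = f, info = info, n_sequences = n),
    class = "kinase_pwm"
  )
}

#' @export
print.kinase_pwm <- function(x, ...) {
  consensus <- paste(colnames(x$f)[max.col(x$f)], collapse = "")
  cat("kinase_pwm", if (!is.null(x$kinase)) paste0(" [", x$kinase, "]"),
      ": ", x$n_sequences, " sequences, consensus ", consensus, "\n", sep = "")
  invisible(x)
}

#' Build the PWM library for a kinase-substrate network
#'
#' One PWM per kinase with at least `min_substrates` substrate flanking
#' windows resolvable in the sequence set; kinases below the cutoff are
#' skipped (reported via `message`).
#'
#' @param network a [ks_network()]
#' @param seqs protein sequences (named character or `AAStringSet`)
#' @inheritParams build_pwm
#' @param min_substrates minimum windows per kinase (default 10)
#' @return named list of `kinase_pwm` objects
#' @export
build_pwm_library <- function(network, seqs, min_substrates = 10,
                              pseudocount = 0.01) {
  stopifnot(inherits(network, "ks_network"))
  per_kin <- split(network[, c("protein", "position", "residue")],
                   network$kinase)
  skipped <- character()
  out <- list()
  for (kin in names(per_kin)) {
    sites <- unique(per_kin[[kin]])
    fl <- suppressWarnings(extract_flanks(sites, seqs))
    if (nrow(fl) < min_substrates) {
      skipped <- c(skipped, kin)
      next
    }
    out[[kin]] <- build_pwm(fl$window, pseudocount = pseudocount,
                            min_sequences = min_substrates, kinase = kin)
  }
  if (length(skipped)) {
    message("no PWM for ", length(skipped), " kinase(s) with < ",
            min_substrates, " resolvable substrates: ",
            paste(skipped, collapse = ", "))
  }
  out
}

#' Matrix similarity score between windows and a PWM
#'
#' MATCH-style information-weighted score, min-max normalized to `[0, 1]`:
#' `Current = sum_i I(i) f(i, b_i)`, `Min = sum_i I(i) min_b f(i, b)`,
#' `Max = sum_i I(i) max_b f(i, b)`, `mss = (Current - Min) / (Max - Min)`.
#' A score of 1 means the window matches the consensus letter at every
#' informative position; 0 means the least-preferred letter everywhere. For
#' a zero-information matrix (`Max == Min`) the score is defined as 1, with
#' a warning.
#'
#' @param pwm a `kinase_pwm` from [build_pwm()]
#' @param windows character vector of 15-letter windows
#' @return numeric vector of scores in `[0, 1]`
#' @export
mss <- function(pwm, windows) {
  stopifnot(inherits(pwm, "kinase_pwm"))
  if (is.data.frame(windows)) windows <- windows$window
  if (any(nchar(windows) != WINDOW)) {
    stop("windows must have length ", WINDOW, call. = FALSE)
  }
  I <- pwm$info
  lo <- sum(I * apply(pwm$f, 1, min))
  hi <- sum(I * apply(pwm$f, 1, max))
  if (hi == lo) {
    warning("zero-information matrix: MSS defined as 1", call. = FALSE)
    return(rep(1, length(windows)))
  }
  mat <- do.call(rbind, strsplit(windows, ""))
  mat[!(mat %in% PWM_ALPHABET)] <- PAD
  idx <- matrix(match(mat, PWM_ALPHABET), nrow = length(windows))
  cur <- vapply(seq_len(length(windows)), function(r) {
    sum(I * pwm$f[cbind(seq_len(WINDOW), idx[r, ])])
  }, numeric(1))
  (cur - lo) / (hi - lo)
}

#' MSS of every network substrate against its kinase's PWM
#'
#' @param network a [ks_network()]
#' @param pwm_library named list from [build_pwm_library()]
#' @param seqs protein sequences
#' @return data.frame `(kinase, site, mss)` where `site` is the residue-free
#'   match key
#' @export
mss_table <- function(network, pwm_library, seqs) {
  stopifnot(inherits(network, "ks_network"))
  per_kin <- split(network[, c("protein", "position", "residue")],
                   network$kinase)
  per_kin <- per_kin[names(per_kin) %in% names(pwm_library)]
  pieces <- lapply(names(per_kin), function(kin) {
    sites <- unique(per_kin[[kin]])
    fl <- suppressWarnings(extract_flanks(sites, seqs))
    if (nrow(fl) == 0) return(NULL)
    data.frame(
      kinase = kin,
      site = match_key(fl$protein, fl$position),
      mss = mss(pwm_library[[kin]], fl$window),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Weight substrate fold changes by their matrix similarity scores
#'
#' Multiplies the fold change of each quantified regulon site by its MSS;
#' all other fold changes are unaltered. The weighted vector feeds the
#' Z-test or the enrichment score to give the `ztest_weighted` /
#' `gsea_weighted` methods.
#'
#' @param fc named fold-change vector from [condition_fc()]
#' @param substrates regulon site keys
#' @param mss_values named numeric vector, site key -> MSS
#' @return fold-change vector with weighted substrate entries
#' @export
weight_fold_changes <- function(fc, substrates, mss_values) {
  is_sub <- names(fc) %in% substrates
  sub_keys <- names(fc)[is_sub]
  missing <- setdiff(sub_keys, names(mss_values))
  if (length(missing)) {
    stop("no MSS available for quantified substrate site(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  fc[is_sub] <- fc[is_sub] * mss_values[sub_keys]
  fc
}
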