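# Kinase-substrate network: container, filters, degree-preserving nulls.

EVIDENCE_CLASSES <- c("in_vivo", "in_vitro", "in_silico")

#' Kinase-substrate network
#'
#' A set of kinase -> phosphosite interactions. Each interaction carries the
#' substrate protein, 1-based site position, phosphoacceptor residue, an
#' evidence class (`in_vivo`, `in_vitro` or `in_silico`) and, for in silico
#' edges, an optional prediction score. Exact duplicate
#' (kinase, protein, position, evidence) rows are merged; the same site
#' supported by several evidence classes is kept as one interaction per
#' class.
#'
#' @param interactions data.frame with columns `kinase`, `protein`,
#'   `position`, `residue`, `evidence` and optionally `score`
#' @return object of class `ks_network` (a data.frame)
#' @export
ks_network <- function(interactions) {
  stopifnot(is.data.frame(interactions))
  need <- c("kinase", "protein", "position", "residue", "evidence")
  miss <- setdiff(need, names(interactions))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x <- interactions
  x$position <- as.integer(x$position)
  if (any(is.na(x$position) | x$position < 1)) {
    stop("site positions must be integers >= 1", call. = FALSE)
  }
  bad <- setdiff(unique(x$evidence), EVIDENCE_CLASSES)
  if (length(bad)) {
    stop("unknown evidence class(es): ", paste(bad, collapse = ", "),
         " (expected ", paste(EVIDENCE_CLASSES, collapse = "/"), ")",
         call. = FALSE)
  }
  if (is.null(x$score)) x$score <- NA_real_
  dup <- duplicated(x[, c("kinase", "protein", "position", "evidence")])
  x <- x[!dup, c("kinase", "protein", "position", "residue", "evidence", "score")]
  rownames(x) <- NULL
  class(x) <- c("ks_network", "data.frame")
  x
}

#' @export
print.ks_network <- function(x, ...) {
  cat("ks_network: ", nrow(x), " interactions, ",
      length(unique(x$kinase)), " kinases, ",
      length(unique(match_key(x$protein, x$position))), " sites\n", sep = "")
  invisible(x)
}

#' Read a kinase-substrate network TSV
#'
#' Expects columns `kinase`, `protein`, `position`, `residue`, `evidence`
#' (and optionally `score`). Duplicate rows are merged.
#'
#' @param path TSV file with header
#' @return [ks_network()]
#' @export
read_ks_network <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ks_network(df)
}

#' Kinase regulons as residue-free site keys
#'
#' @param network a [ks_network()]
#' @return named list, kinase -> character vector of unique
#'   `PROTEIN_POSITION` keys
#' @export
regulons <- function(network) {
  stopifnot(inherits(network, "ks_network"))
  keys <- match_key(network$protein, network$position)
  lapply(split(keys, network$kinase), unique)
}

#' Regulon sizes
#' @param network a [ks_network()]
#' @return named integer vector of unique-substrate counts per kinase
#' @export
regulon_sizes <- function(network) {
  lengths(regulons(network))
}

#' Remove autoregulatory interactions
#'
#' Drops interactions where the substrate protein is the kinase's own
#' protein; such direct regulatory phosphorylations would otherwise bias the
#' activity inference with trivial self-signal. Kinases absent from the
#' mapping keep their interactions, with a warning.
#'
#' @param network a [ks_network()]
#' @param kinase_to_protein named character vector mapping kinase id to its
#'   own protein accession
#' @return filtered `ks_network`
#' @export
exclude_autoregulatory <- function(network, kinase_to_protein) {
  stopifnot(inherits(network, "ks_network"))
  if (nrow(network) == 0) return(network)
  own <- kinase_to_protein[network$kinase]
  unmapped <- is.na(own)
  if (any(unmapped)) {
    warning("no protein mapping for kinase(s): ",
            paste(unique(network$kinase[unmapped]), collapse = ", "),
            "; their interactions are retained", call. = FALSE)
  }
  drop <- !unmapped & network$protein == own
  out <- network[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ks_network", "data.frame")
  out
}

#' Keep kinases with at least k substrates
#'
#' @param network a [ks_network()]
#' @param k minimum number of unique substrate sites per kinase
#' @return filtered `ks_network`
#' @export
filter_min_substrates <- function(network, k) {
  stopifnot(inherits(network, "ks_network"), k >= 1)
  sizes <- regulon_sizes(network)
  keep <- names(sizes)[sizes >= k]
  out <- network[network$kinase %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ks_network", "data.frame")
  out
}

#' Filter by evidence class and in silico prediction score
#'
#' @param network a [ks_network()]
#' @param classes evidence classes to keep (default: all)
#' @param min_score optional minimum prediction score; interactions with a
#'   recorded score below it are dropped (unscored interactions are kept)
#' @return filtered `ks_network`
#' @export
filter_evidence <- function(network, classes = EVIDENCE_CLASSES,
                            min_score = NULL) {
  stopifnot(inherits(network, "ks_network"))
  classes <- match.arg(classes, EVIDENCE_CLASSES, several.ok = TRUE)
  out <- network[network$evidence %in% classes, , drop = FALSE]
  if (!is.null(min_score)) {
    out <- out[is.na(out$score) | out$score >= min_score, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("ks_network", "data.frame")
  out
}

#' Degree-preserving network randomization
#'
#' Replaces every kinase's substrate set with a uniform sample (without
#' replacement) from the site universe of the same size as the original
#' regulon. Kinases are sampled independently, so two kinases may share
#' sites, as in the real network. This serves as the technical-noise control:
#' inference against randomized networks should collapse to chance
#' performance.
#'
#' @param network a [ks_network()]
#' @param site_universe character vector of `PROTEIN_POSITION` match keys,
#'   or a data.frame with `protein`, `position` (and optionally `residue`)
#' @param seed integer seed for reproducibility
#' @return randomized `ks_network` with identical regulon sizes
#' @export
randomize_preserving_degree <- function(network, site_universe, seed = NULL) {
  stopifnot(inherits(network, "ks_network"))
  if (is.data.frame(site_universe)) {
    uni <- data.frame(
      protein = site_universe$protein,
      position = as.integer(site_universe$position),
      residue = site_universe$residue %||% rep(NA_character_, nrow(site_universe)),
      stringsAsFactors = FALSE
    )
  } else {
    parts <- strsplit(site_universe, "_", fixed = TRUE)
    np <- lengths(parts)
    uni <- data.frame(
      protein = vapply(seq_along(parts), function(i)
        paste(parts[[i]][seq_len(np[i] - 1L)], collapse = "_"), character(1)),
      position = as.integer(vapply(parts, function(p) p[length(p)], character(1))),
      residue = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  uni <- uni[!duplicated(match_key(uni$protein, uni$position)), , drop = FALSE]
  sizes <- regulon_sizes(network)
  if (any(sizes > nrow(uni))) {
    stop("regulon larger than the site universe: ",
         paste(names(sizes)[sizes > nrow(uni)], collapse = ", "), call. = FALSE)
  }
  maybe_set_seed(seed)
  pieces <- lapply(names(sizes), function(kin) {
    idx <- sample.int(nrow(uni), sizes[[kin]])
    ev <- network$evidence[network$kinase == kin]
    data.frame(
      kinase = kin,
      protein = uni$protein[idx],
      position = uni$position[idx],
      residue = ifelse(is.na(uni$residue[idx]), "S", uni$residue[idx]),
      evidence = rep_len(ev, length(idx)),
      score = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  ks_network(do.call(rbind, pieces))
}
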