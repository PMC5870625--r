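# Parsing, filtering and normalization of site-level phosphoproteomic tables.

#' Default column-name mapping for phosphopeptide tables
#'
#' Maps the logical fields of a phosphopeptide record to column names in a
#' TSV file. `positions` and `residues` may contain several values separated
#' by `;` for multiply phosphorylated peptides. `replicate`, `canonical` and
#' `peptide` are optional in the file; absent columns default to a single
#' replicate, canonical mapping, and no peptide identity.
#'
#' @return named list of column names
#' @export
default_dialect <- function() {
  list(
    protein = "protein", positions = "positions", residues = "residues",
    condition = "condition", replicate = "replicate", log2fc = "log2fc",
    canonical = "canonical", peptide = "peptide"
  )
}

#' Read a phosphopeptide quantification table
#'
#' Parses a TSV of peptide-level log2 fold changes into one record per row.
#' Malformed rows (position/residue length mismatch, unparseable positions)
#' and non-numeric fold changes are collected and reported with their line
#' numbers; they are only fatal when more than half of the rows fail.
#'
#' @param path TSV file with a header row
#' @param dialect named list overriding entries of [default_dialect()]
#' @return data.frame of records with columns `protein`, `positions`
#'   (`;`-joined), `residues`, `n_sites`, `condition`, `replicate`, `log2fc`,
#'   `canonical`, `peptide`
#' @export
read_phospho_table <- function(path, dialect = list()) {
  dia <- utils::modifyList(default_dialect(), dialect)
  raw <- read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL)
  required <- c("protein", "positions", "residues", "condition", "log2fc")
  for (f in required) {
    if (!dia[[f]] %in% names(raw)) {
      stop("required column '", dia[[f]], "' (field '", f, "') not found in ",
           path, call. = FALSE)
    }
  }
  n <- nrow(raw)
  get_opt <- function(field, default) {
    if (dia[[field]] %in% names(raw)) raw[[dia[[field]]]] else rep(default, n)
  }
  rec <- data.frame(
    protein   = raw[[dia$protein]],
    positions = raw[[dia$positions]],
    residues  = raw[[dia$residues]],
    condition = raw[[dia$condition]],
    replicate = get_opt("replicate", "r1"),
    log2fc    = suppressWarnings(as.numeric(raw[[dia$log2fc]])),
    canonical = toupper(get_opt("canonical", "TRUE")) %in% c("TRUE", "T", "1", "YES"),
    peptide   = get_opt("peptide", NA_character_),
    stringsAsFactors = FALSE
  )
  if (n == 0) return(rec[0, ])

  pos_list <- strsplit(rec$positions, ";", fixed = TRUE)
  res_list <- strsplit(rec$residues, ";", fixed = TRUE)
  pos_num <- lapply(pos_list, function(p) suppressWarnings(as.numeric(p)))
  bad <- vapply(seq_len(n), function(i) {
    p <- pos_num[[i]]
    length(p) == 0 || anyNA(p) || any(p < 1) || is.unsorted(p, strictly = TRUE) ||
      length(p) != length(res_list[[i]])
  }, logical(1))
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) dropped (lines ",
            paste(which(bad) + 1L, collapse = ", "), ")", call. = FALSE)
  }
  fc_na <- is.na(rec$log2fc) & !bad
  if (any(fc_na)) {
    warning(sum(fc_na), " row(s) with non-numeric log2fc kept as missing (lines ",
            paste(utils::head(which(fc_na) + 1L, 20), collapse = ", "), ")",
            call. = FALSE)
  }
  if (sum(bad) > n / 2) {
    stop("more than 50% of rows are malformed; refusing to parse ", path,
         call. = FALSE)
  }
  rec$n_sites <- lengths(pos_list)
  rec <- rec[!bad, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Site-by-condition quantification matrix
#'
#' Container for the preprocessed fold-change matrix. `values` is a numeric
#' matrix (rows: sites keyed `PROTEIN_POSITION_RESIDUE`; columns: conditions)
#' with `NA` for unquantified entries; `sites` records the parsed key parts
#' including the residue-free `match_key` used to join the kinase-substrate
#' network.
#'
#' @param values numeric matrix with site-key rownames and condition colnames
#' @param sites data.frame with columns `protein`, `position`, `residue`
#'   (optional; parsed from rownames when missing)
#' @param normalized logical, whether quantile normalization was applied
#' @return object of class `site_quant`
#' @export
site_quant <- function(values, sites = NULL, normalized = FALSE) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate site keys", call. = FALSE)
  if (is.null(sites)) {
    parts <- strsplit(rownames(values), "_", fixed = TRUE)
    np <- lengths(parts)
    sites <- data.frame(
      protein = vapply(seq_along(parts), function(i)
        paste(parts[[i]][seq_len(np[i] - 2L)], collapse = "_"), character(1)),
      position = as.integer(vapply(parts, function(p) p[length(p) - 1L], character(1))),
      residue = vapply(parts, function(p) p[length(p)], character(1)),
      stringsAsFactors = FALSE
    )
  }
  sites$key <- rownames(values)
  sites$match_key <- match_key(sites$protein, sites$position)
  structure(
    list(values = values, sites = sites, conditions = colnames(values),
         normalized = normalized),
    class = "site_quant"
  )
}

#' @export
print.site_quant <- function(x, ...) {
  cat("site_quant: ", nrow(x$values), " sites x ", ncol(x$values),
      " conditions (", if (x$normalized) "quantile-normalized" else "unnormalized",
      "); ", round(100 * mean(is.na(x$values)), 1), "% missing\n", sep = "")
  invisible(x)
}

#' @export
dim.site_quant <- function(x) dim(x$values)

#' Collapse phosphopeptide records to a site-level fold-change matrix
#'
#' Applies, in order: (i) drop records not mapped to the canonical transcript;
#' (ii) keep only monophosphorylated peptides, so each fold change is
#' attributable to a single site; (iii) average log2 fold changes across
#' replicates of the same peptide and condition; (iv) average across distinct
#' peptides covering the same site and condition; (v) drop conditions with
#' fewer than `min_coverage` quantified sites. When records carry no peptide
#' identity, steps (iii) and (iv) collapse in a single mean per
#' (site, condition).
#'
#' @param records data.frame as returned by [read_phospho_table()]
#' @param min_coverage minimum quantified sites per retained condition
#'   (default 1000, the coverage cutoff used for curated benchmark studies)
#' @return unnormalized [site_quant()] matrix
#' @export
preprocess_records <- function(records, min_coverage = 1000) {
  stopifnot(is.data.frame(records))
  if (is.null(records$n_sites)) {
    records$n_sites <- lengths(strsplit(records$positions, ";", fixed = TRUE))
  }
  if (is.null(records$peptide)) records$peptide <- NA_character_
  if (is.null(records$replicate)) records$replicate <- "r1"
  if (is.null(records$canonical)) records$canonical <- TRUE

  rec <- records[records$canonical & records$n_sites == 1L, , drop = FALSE]
  rec <- rec[!is.na(rec$log2fc), , drop = FALSE]
  if (nrow(rec) == 0) stop("no records survive the canonical/monophospho filters",
                           call. = FALSE)
  key <- site_key(rec$protein, rec$positions, rec$residues)

  if (any(!is.na(rec$peptide))) {
    # replicate-first: mean over replicates within (site, condition, peptide),
    # then mean over peptides within (site, condition)
    g1 <- paste(key, rec$condition, rec$peptide, sep = "\r")
    m1 <- tapply(rec$log2fc, g1, mean)
    parts <- strsplit(names(m1), "\r", fixed = TRUE)
    g2 <- vapply(parts, function(p) paste(p[1], p[2], sep = "\r"), character(1))
    m2 <- tapply(as.numeric(m1), g2, mean)
    agg_keys <- strsplit(names(m2), "\r", fixed = TRUE)
    vals <- as.numeric(m2)
  } else {
    g2 <- paste(key, rec$condition, sep = "\r")
    m2 <- tapply(rec$log2fc, g2, mean)
    agg_keys <- strsplit(names(m2), "\r", fixed = TRUE)
    vals <- as.numeric(m2)
  }
  skey <- vapply(agg_keys, `[`, character(1), 1L)
  cond <- vapply(agg_keys, `[`, character(1), 2L)

  usites <- sort(unique(skey))
  uconds <- sort(unique(cond))
  m <- matrix(NA_real_, length(usites), length(uconds),
              dimnames = list(usites, uconds))
  m[cbind(match(skey, usites), match(cond, uconds))] <- vals

  counts <- colSums(!is.na(m))
  keep <- counts >= min_coverage
  if (!any(keep)) {
    stop("all conditions fall below min_coverage=", min_coverage,
         " quantified sites (counts: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(!keep)) {
    message("dropping ", sum(!keep), " condition(s) below coverage cutoff: ",
            paste(names(counts)[!keep], collapse = ", "))
  }
  m <- m[, keep, drop = FALSE]
  m <- m[rowSums(!is.na(m)) > 0, , drop = FALSE]
  site_quant(m, normalized = FALSE)
}

#' Quantile normalization across conditions
#'
#' Classical quantile normalization of the condition columns against a shared
#' reference distribution. Each column's observed (non-missing) values are
#' ranked (average ranks for ties) and mapped onto the reference, defined as
#' the mean of the per-column sorted observed values interpolated to a common
#' grid whose length equals the largest observed count. Missing entries stay
#' missing. Columns with equal numbers of observed values end up with
#' identical sorted values.
#'
#' @param m unnormalized [site_quant()] matrix
#' @return normalized `site_quant`
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "site_quant"))
  if (m$normalized) stop("matrix is already quantile-normalized", call. = FALSE)
  v <- m$values
  if (ncol(v) < 2) {
    warning("single-condition matrix: quantile normalization is a no-op",
            call. = FALSE)
    m$normalized <- TRUE
    return(m)
  }
  counts <- colSums(!is.na(v))
  if (any(counts == 0)) stop("condition with no observed values", call. = FALSE)
  n_max <- max(counts)
  grid <- seq(0, 1, length.out = n_max)
  stretched <- vapply(seq_len(ncol(v)), function(j) {
    o <- sort(v[!is.na(v[, j]), j])
    if (length(o) == 1) return(rep(o, n_max))
    approx(seq(0, 1, length.out = length(o)), o, xout = grid)$y
  }, numeric(n_max))
  ref <- rowMeans(stretched)
  out <- v
  for (j in seq_len(ncol(v))) {
    obs <- !is.na(v[, j])
    n_j <- counts[j]
    target <- if (n_j == n_max) ref else {
      approx(grid, ref, xout = seq(0, 1, length.out = n_j))$y
    }
    r <- rank(v[obs, j], ties.method = "average")
    out[obs, j] <- if (n_j == 1) target else approx(seq_len(n_j), target, xout = r)$y
  }
  m$values <- out
  m$normalized <- TRUE
  m
}

#' Write / read a site-by-condition matrix as TSV
#'
#' Row key column `site` holds `PROTEIN_POSITION_RESIDUE`; missing values are
#' written as empty fields.
#'
#' @param m a [site_quant()] object
#' @param path output TSV path
#' @export
write_quant_matrix <- function(m, path) {
  stopifnot(inherits(m, "site_quant"))
  df <- data.frame(site = rownames(m$values), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_quant_matrix
#' @param normalized whether the stored matrix was normalized
#' @export
read_quant_matrix <- function(path, normalized = FALSE) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   na.strings = c("", "NA"))
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  site_quant(v, normalized = normalized)
}

#' Expand a quantification matrix back into per-row records
#'
#' One record per non-missing cell (single replicate, canonical, no peptide
#' identity). Useful to feed simulated matrices through the preprocessing
#' path.
#'
#' @param m a [site_quant()] object
#' @return records data.frame compatible with [preprocess_records()]
#' @export
quant_to_records <- function(m) {
  stopifnot(inherits(m, "site_quant"))
  idx <- which(!is.na(m$values), arr.ind = TRUE)
  data.frame(
    protein = m$sites$protein[idx[, 1]],
    positions = as.character(m$sites$position[idx[, 1]]),
    residues = m$sites$residue[idx[, 1]],
    condition = m$conditions[idx[, 2]],
    replicate = "r1",
    log2fc = m$values[idx],
    canonical = TRUE,
    peptide = NA_character_,
    n_sites = 1L,
    stringsAsFactors = FALSE
  )
}
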