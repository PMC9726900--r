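#' Read a crosslink table
#'
#' Delimited text (tab or comma, auto-detected) with columns `protein_i`,
#' `pos_i`, `protein_j`, `pos_j` and optionally `score`.  Crosslinks are
#' identified by their unordered residue pair within an unordered protein
#' pair, and duplicates are removed.
#'
#' @param path file path.
#' @return A data frame of class `xl_table` with canonicalized unique
#'   crosslinks and attributes `n_rows_raw` and `n_duplicates`.
#' @export
read_xl_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  xl_table(df)
}

#' @rdname read_xl_table
#' @param df data frame with the crosslink columns.
#' @export
xl_table <- function(df) {
  need <- c("protein_i", "pos_i", "protein_j", "pos_j")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_remkin("format_error",
                paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  if (!nrow(df)) {
    out <- df[, intersect(c(need, "score"), names(df)), drop = FALSE]
    return(structure(out, n_rows_raw = 0L, n_duplicates = 0L,
                     class = c("xl_table", "data.frame")))
  }
  if (any(df$pos_i < 1) || any(df$pos_j < 1)) {
    stop_remkin("domain_error", "residue positions must be >= 1")
  }
  n_raw <- nrow(df)
  # canonical order: protein pair sorted, then positions sorted within it
  swap <- df$protein_i > df$protein_j |
    (df$protein_i == df$protein_j & df$pos_i > df$pos_j)
  tmp_p <- df$protein_i[swap]; tmp_q <- df$pos_i[swap]
  df$protein_i[swap] <- df$protein_j[swap]
  df$pos_i[swap] <- df$pos_j[swap]
  df$protein_j[swap] <- tmp_p
  df$pos_j[swap] <- tmp_q
  key <- paste(df$protein_i, df$pos_i, df$protein_j, df$pos_j)
  dup <- duplicated(key)
  out <- df[!dup, intersect(c(need, "score"), names(df)), drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_rows_raw = n_raw, n_duplicates = sum(dup),
            class = c("xl_table", "data.frame"))
}

#' @rdname read_xl_table
#' @param xls an `xl_table`.
#' @export
write_xl_table <- function(xls, path) {
  utils::write.table(as.data.frame(xls), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Named residue intervals of a protein topology
#'
#' @param ... named length-2 integer vectors `c(start, end)`, 1-based
#'   inclusive.
#' @return A named list of validated intervals (class `region_map`).
#' @export
region_map <- function(...) {
  regions <- list(...)
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    stop_remkin("domain_error", "all regions must be named")
  }
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1) {
      stop_remkin("domain_error",
                  sprintf("region %s must be c(start, end) with 1 <= start <= end", nm))
    }
  }
  structure(regions, class = "region_map")
}

#' Region map for the CHD4 domain topology
#'
#' Named intervals in full-length numbering (UniProt Q14839, 1912
#' residues).  Two conventions for the auto-inhibitory C1a region are in
#' circulation and both ship: `C1a` (1231-1380, the truncation boundary)
#' and `C1a_xl` (1201-1340, the interval used when tallying crosslinks
#' touching the region).
#'
#' @param seq_length full protein length.
#' @return A [region_map].
#' @export
chd4_regions <- function(seq_length = 1912) {
  region_map(
    IDR1 = c(1, 144),
    HMG = c(145, 226),
    IDR2 = c(227, 362),
    C1a = c(1231, 1380),
    C1a_xl = c(1201, 1340),
    C1b = c(1381, 1551),
    C2a = c(1690, 1810),
    C2b = c(seq_length - 101, seq_length)
  )
}

#' Filter crosslinks by region
#'
#' @param xls an [xl_table] (or compatible data frame).
#' @param region length-2 interval `c(start, end)` or a name into a
#'   [region_map] supplied as `regions`.
#' @param mode `"either_end"` keeps crosslinks with at least one endpoint
#'   inside the inclusive interval; `"both_ends"` requires both.
#' @param regions optional [region_map] to resolve a region name.
#' @return The filtered `xl_table` subset.
#' @export
filter_by_region <- function(xls, region, mode = c("either_end", "both_ends"),
                             regions = NULL) {
  mode <- match.arg(mode)
  if (is.character(region)) {
    if (is.null(regions)) regions <- chd4_regions()
    if (!region %in% names(regions)) {
      stop_remkin("domain_error", paste("unknown region:", region))
    }
    region <- regions[[region]]
  }
  if (length(region) != 2L || region[1L] > region[2L]) {
    stop_remkin("domain_error", "region must be c(start, end) with start <= end")
  }
  in_i <- xls$pos_i >= region[1L] & xls$pos_i <= region[2L]
  in_j <- xls$pos_j >= region[1L] & xls$pos_j <= region[2L]
  keep <- if (mode == "either_end") in_i | in_j else in_i & in_j
  out <- xls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' C-alpha coordinate model
#'
#' @param coords numeric matrix (n x 3) of C-alpha coordinates in
#'   Angstroms.
#' @param positions residue numbers for the rows (unique).
#' @param chain chain identifier.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(coords, positions = seq_len(nrow(coords)),
                            chain = "A") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || any(!is.finite(coords))) {
    stop_remkin("domain_error", "coords must be a finite n x 3 matrix")
  }
  if (length(positions) != nrow(coords) || anyDuplicated(positions)) {
    stop_remkin("domain_error", "positions must be unique and match coords rows")
  }
  rownames(coords) <- as.character(positions)
  structure(list(coords = coords, positions = as.integer(positions),
                 chain = chain),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> chain %s: %d residues (%d-%d)\n", x$chain,
              nrow(x$coords), min(x$positions), max(x$positions)))
  invisible(x)
}

#' Read C-alpha coordinates from a PDB or mmCIF file
#'
#' @param path file path (`.pdb` or `.cif`).
#' @param chain chain identifier; default: the first chain in the file.
#' @return A [structure_model].
#' @export
read_structure <- function(path, chain = NULL) {
  pdb <- if (grepl("\\.cif$", path, ignore.case = TRUE)) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) stop_remkin("format_error", "no C-alpha atoms in file")
  if (is.null(chain)) chain <- ca$chain[1L]
  ca <- ca[ca$chain == chain, , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  structure_model(as.matrix(ca[, c("x", "y", "z")]),
                  positions = ca$resno, chain = chain)
}

#' C-alpha to C-alpha distance
#'
#' Euclidean distance between residue positions in a structural model;
#' `NA` where a residue is not resolved in the model (counted separately
#' downstream, not an error).
#'
#' @param model a [structure_model].
#' @param i,j residue positions (vectorized).
#' @return Distances in Angstroms.
#' @export
ca_distance <- function(model, i, j) {
  stopifnot(inherits(model, "structure_model"))
  ci <- model$coords[match(as.character(i), rownames(model$coords)), ,
                     drop = FALSE]
  cj <- model$coords[match(as.character(j), rownames(model$coords)), ,
                     drop = FALSE]
  unname(sqrt(rowSums((ci - cj)^2)))
}

#' Crosslink satisfaction against a structural model
#'
#' Scores each crosslink by its C-alpha distance in the model; a
#' crosslink is satisfied when the distance is strictly below `cutoff`.
#' Crosslinks with an unresolved endpoint are reported separately and
#' excluded from the satisfaction fraction's denominator (models routinely
#' omit disordered regions; treating missingness as violation would
#' conflate the two) -- the fraction over all crosslinks is also reported.
#'
#' @param xls an [xl_table].
#' @param model a [structure_model].
#' @param cutoff compatibility distance in Angstroms (strict `<`).
#' @param bin_width histogram bin width in Angstroms.
#' @return An object of class `xl_satisfaction`: `fraction_satisfied`
#'   (over resolved crosslinks), `fraction_all` (unresolved counted as
#'   unsatisfied), `n_resolved`, `n_unresolved`, `table` (per-crosslink
#'   distances and flags) and `histogram` (distance distribution).
#' @export
satisfaction_report <- function(xls, model, cutoff = 35, bin_width = 5) {
  if (!nrow(xls)) stop_remkin("empty_report", "no crosslinks to score")
  d <- ca_distance(model, xls$pos_i, xls$pos_j)
  resolved <- !is.na(d)
  if (!any(resolved)) {
    stop_remkin("empty_report", "model shares no residues with the crosslinks")
  }
  satisfied <- d < cutoff
  tab <- data.frame(pos_i = xls$pos_i, pos_j = xls$pos_j, distance = d,
                    resolved = resolved, satisfied = satisfied)
  breaks <- seq(0, max(d[resolved], cutoff) + bin_width, by = bin_width)
  counts <- as.integer(table(cut(d[resolved], breaks = breaks,
                                 right = FALSE)))
  structure(
    list(fraction_satisfied = mean(satisfied[resolved]),
         fraction_all = sum(satisfied, na.rm = TRUE) / nrow(xls),
         n_resolved = sum(resolved), n_unresolved = sum(!resolved),
         cutoff = cutoff, table = tab,
         histogram = data.frame(lower = utils::head(breaks, -1L),
                                upper = utils::tail(breaks, -1L),
                                count = counts)),
    class = "xl_satisfaction"
  )
}

#' @export
print.xl_satisfaction <- function(x, ...) {
  cat(sprintf(
    "<xl_satisfaction> %.1f%% of %d resolved crosslinks < %g A (%d unresolved)\n",
    100 * x$fraction_satisfied, x$n_resolved, x$cutoff, x$n_unresolved))
  invisible(x)
}

#' Lint crosslink endpoints for BS3 reactivity
#'
#' Opt-in check that each crosslinked residue is a BS3-reactive site
#' (Lys, Ser, Thr, Tyr) or the protein N-terminus.  Deposited lists are
#' trusted by default; this helper flags entries that violate the
#' chemistry.
#'
#' @param xls an [xl_table].
#' @param sequence protein sequence in full-length numbering.
#' @param reactive reactive residue one-letter codes.
#' @return The `xl_table` with logical columns `ok_i`, `ok_j`.
#' @export
lint_bs3_sites <- function(xls, sequence, reactive = c("K", "S", "T", "Y")) {
  chars <- check_aa_sequence(sequence)
  site_ok <- function(pos) {
    pos == 1L | (pos <= length(chars) & chars[pmin(pos, length(chars))] %in% reactive)
  }
  out <- as.data.frame(xls)
  out$ok_i <- site_ok(out$pos_i)
  out$ok_j <- site_ok(out$pos_j)
  out
}
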