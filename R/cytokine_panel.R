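#' Construct a cytokine panel
#'
#' A cytokine panel couples a samples-by-analytes concentration matrix (pg/mL)
#' with per-sample metadata. This is the universal input container of the
#' package: every downstream step (scaling, model fitting, stability
#' profiling, univariate screens) consumes a `cytokine_panel`.
#'
#' @param concentrations Numeric matrix, rows = samples, columns = analytes.
#'   Row names are sample ids, column names analyte names. Values are
#'   concentrations in pg/mL; `NA` marks a missing (e.g. out-of-range)
#'   measurement. All non-missing values must be non-negative.
#' @param metadata Data frame with one row per sample. Must contain a
#'   `sample_id` column (or row names) covering every row of
#'   `concentrations`; typical columns are `group`, `species`, `compartment`,
#'   `sex`, `age`, plus optional clinical score columns.
#' @return An object of class `cytokine_panel` with elements `x`
#'   (concentration matrix) and `meta` (metadata, aligned row-for-row with
#'   `x`).
#' @examples
#' x <- matrix(abs(rnorm(12, 50, 10)), 4, 3,
#'             dimnames = list(paste0("s", 1:4), c("IL-6", "TNF-a", "IP-10")))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    group = c("CTRL", "CTRL", "MLIV", "MLIV"))
#' p <- cytokine_panel(x, meta)
#' p
#' @export
cytokine_panel <- function(concentrations, metadata) {
  x <- as.matrix(concentrations)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) stop("concentrations must have sample ids as row names")
  if (ncol(x) > 0 && is.null(colnames(x)))
    stop("concentrations must have analyte names as column names")
  meta <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) {
    if (!is.null(rownames(meta)) && !identical(rownames(meta), as.character(seq_len(nrow(meta))))) {
      meta <- cbind(sample_id = rownames(meta), meta, stringsAsFactors = FALSE)
    } else {
      stop("metadata must contain a 'sample_id' column")
    }
  }
  meta$sample_id <- as.character(meta$sample_id)
  rownames(meta) <- NULL
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample id(s): ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate analyte name(s): ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample id(s) in metadata")
  missing_meta <- setdiff(rownames(x), meta$sample_id)
  if (length(missing_meta))
    stop("metadata row absent for sample(s): ", paste(missing_meta, collapse = ", "))
  meta <- meta[match(rownames(x), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(x < 0, na.rm = TRUE))
    stop("negative concentration(s) found; concentrations must be >= 0 pg/mL")
  structure(list(x = x, meta = meta), class = "cytokine_panel")
}

#' @export
print.cytokine_panel <- function(x, ...) {
  cat(sprintf("<cytokine_panel> %d samples x %d analytes\n", nrow(x$x), ncol(x$x)))
  nmiss <- sum(is.na(x$x))
  if (nmiss) cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss, 100 * nmiss / length(x$x)))
  grp <- panel_column(x, c("group", "group_label"), required = FALSE)
  if (!is.null(grp)) {
    tab <- table(grp)
    cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  cat("  analytes:", paste(utils::head(colnames(x$x), 6), collapse = ", "),
      if (ncol(x$x) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.cytokine_panel <- function(x) dim(x$x)

# fetch a metadata column by any of several accepted names
panel_column <- function(panel, names_try, required = TRUE) {
  hit <- intersect(names_try, names(panel$meta))
  if (!length(hit)) {
    if (required) stop("metadata column not found (tried: ",
                       paste(names_try, collapse = ", "), ")")
    return(NULL)
  }
  panel$meta[[hit[[1]]]]
}

#' Subset a cytokine panel
#'
#' @param x A `cytokine_panel`.
#' @param samples,analytes Logical, integer or character index of samples /
#'   analytes to keep; `NULL` keeps all.
#' @param ... Unused.
#' @return A `cytokine_panel` restricted to the requested rows/columns.
#' @export
subset_panel <- function(x, samples = NULL, analytes = NULL, ...) {
  stopifnot(inherits(x, "cytokine_panel"))
  if (is.null(samples)) samples <- seq_len(nrow(x$x))
  if (is.null(analytes)) analytes <- seq_len(ncol(x$x))
  cytokine_panel(x$x[samples, analytes, drop = FALSE],
                 x$meta[if (is.logical(samples)) which(samples) else
                          if (is.character(samples)) match(samples, x$meta$sample_id) else samples,
                        , drop = FALSE])
}

delim_for_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a cytokine panel from delimited text
#'
#' Reads a samples-by-analytes concentration table plus a sample metadata
#' table. The delimiter is auto-detected from the file extension (`.csv` =
#' comma, anything else = tab); `NA` or empty cells are read as missing.
#' The first column of each file is the sample id; metadata must cover every
#' sample in the concentration table. Sample order follows the concentration
#' file.
#'
#' @param table_path Path to the concentration table (header row = analyte
#'   names, first column = sample id).
#' @param metadata_path Path to the metadata table keyed by sample id.
#' @return A validated [cytokine_panel()].
#' @export
read_panel <- function(table_path, metadata_path) {
  for (p in c(table_path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p)
  tab <- utils::read.table(table_path, header = TRUE, sep = delim_for_path(table_path),
                           na.strings = c("NA", ""), check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample id(s) in ", table_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  x <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  meta <- utils::read.table(metadata_path, header = TRUE, sep = delim_for_path(metadata_path),
                            na.strings = c("NA", ""), check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "\"",
                            comment.char = "", fileEncoding = "UTF-8")
  names(meta)[1] <- "sample_id"
  cytokine_panel(x, meta)
}

#' Write a cytokine panel to delimited text
#'
#' Inverse of [read_panel()]; `read_panel(write_panel(...))` reproduces the
#' panel exactly (missing cells written as `NA`).
#'
#' @param panel A `cytokine_panel`.
#' @param table_path,metadata_path Output paths; extension picks the
#'   delimiter as in [read_panel()].
#' @return Invisibly, `c(table_path, metadata_path)`.
#' @export
write_panel <- function(panel, table_path, metadata_path) {
  stopifnot(inherits(panel, "cytokine_panel"))
  tab <- data.frame(sample_id = rownames(panel$x), panel$x,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, table_path, sep = delim_for_path(table_path),
                     row.names = FALSE, quote = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  utils::write.table(panel$meta, metadata_path, sep = delim_for_path(metadata_path),
                     row.names = FALSE, quote = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(c(table_path, metadata_path))
}

norm_name <- function(x) tolower(trimws(x))

#' Read an analyte harmonization map
#'
#' Two-column delimited file pairing analyte names across two panels (e.g.
#' human and mouse kits). Neither side may repeat a name.
#'
#' @param path Path to a two-column delimited file (header required).
#' @return Data frame with columns `name_a`, `name_b`.
#' @export
read_analyte_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = delim_for_path(path),
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "\"", comment.char = "", fileEncoding = "UTF-8")
  if (ncol(m) < 2) stop("analyte map must have two columns")
  analyte_map(m[[1]], m[[2]])
}

#' Construct an analyte harmonization map
#'
#' @param name_a,name_b Equal-length character vectors of analyte names in
#'   the first and second panel.
#' @return Data frame of class `analyte_map`.
#' @export
analyte_map <- function(name_a, name_b) {
  stopifnot(length(name_a) == length(name_b))
  if (anyDuplicated(norm_name(name_a)) || anyDuplicated(norm_name(name_b)))
    stop("analyte map: a name appears twice on one side")
  structure(data.frame(name_a = as.character(name_a), name_b = as.character(name_b),
                       stringsAsFactors = FALSE),
            class = c("analyte_map", "data.frame"))
}

#' Default human-to-mouse analyte name map
#'
#' Covers analyte names shared (directly or via the functional KC/GRO
#' chemokine correspondence) between common human 41-plex and mouse 32-plex
#' cytokine kits. Users analysing full kits should supply their own map.
#'
#' @return An [analyte_map()] with human names in `name_a`, mouse names in
#'   `name_b`.
#' @export
default_analyte_map <- function() {
  shared <- c("IP-10", "MIG", "IL-17", "IL-13", "IL-9", "Eotaxin", "VEGF",
              "IL-1a", "MIP-1b", "GM-CSF", "IFN-g", "TNF-a", "IL-2",
              "IL-12p70", "IL-15", "IL-1b", "IFN-a2", "IL-6")
  analyte_map(c(shared, "GRO"), c(shared, "KC"))
}

#' Restrict two panels to mapped (shared) analytes
#'
#' Used when comparing panels measured with different kits (e.g. a 41-plex
#' human and a 32-plex mouse panel): both panels are restricted to the
#' analytes paired by `map` and their columns put in identical map order, so
#' loadings and signatures are directly comparable analyte-for-analyte.
#' Name matching is case-insensitive after trimming whitespace.
#'
#' @param panel_a,panel_b `cytokine_panel` objects.
#' @param map An [analyte_map()]; `name_a` refers to `panel_a`, `name_b` to
#'   `panel_b`. Pairs whose names are absent from a panel raise an error.
#' @param drop_unmatched If `TRUE`, silently drop map pairs absent from
#'   either panel instead of erroring (useful with the broad
#'   [default_analyte_map()]).
#' @return List with elements `a` and `b`: the restricted panels, columns in
#'   map order (panel A keeps its own analyte names, likewise panel B).
#' @export
harmonize <- function(panel_a, panel_b, map, drop_unmatched = FALSE) {
  stopifnot(inherits(panel_a, "cytokine_panel"), inherits(panel_b, "cytokine_panel"))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!nrow(map)) stop("analyte map is empty")
  ia <- match(norm_name(map[[1]]), norm_name(colnames(panel_a$x)))
  ib <- match(norm_name(map[[2]]), norm_name(colnames(panel_b$x)))
  if (drop_unmatched) {
    keep <- !is.na(ia) & !is.na(ib)
    ia <- ia[keep]; ib <- ib[keep]
  } else {
    if (anyNA(ia))
      stop("analyte(s) not found in panel A: ",
           paste(map[[1]][is.na(ia)], collapse = ", "))
    if (anyNA(ib))
      stop("analyte(s) not found in panel B: ",
           paste(map[[2]][is.na(ib)], collapse = ", "))
  }
  if (!length(ia)) stop("no shared analytes after harmonization (empty intersection)")
  list(a = subset_panel(panel_a, analytes = ia),
       b = subset_panel(panel_b, analytes = ib))
}
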