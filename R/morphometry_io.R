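#' @useDynLib scnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor pt pchisq rnorm runif rbinom sd setNames p.adjust
#' @importFrom utils read.csv read.delim write.table packageVersion modifyList
NULL

.delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else if (ext %in% c("tsv", "txt")) "\t"
  else stop("unsupported file extension '", ext, "' (use .tsv or .csv)")
}

.meta_cols <- c("subject_id", "condition", "group")

#' Validate a thickness table
#'
#' A thickness table is a data frame with columns `subject_id`, `condition`,
#' `group` and one numeric column per atlas ROI (mean cortical thickness in
#' mm). Checks: all ROI columns present and no extraneous columns, all
#' values finite and strictly positive, no duplicated
#' (subject_id, condition) pair. ROI columns are reordered to atlas order.
#'
#' @param tab data frame to validate.
#' @param atlas a [roi_atlas()].
#' @param paired if `TRUE`, additionally require every subject to appear in
#'   exactly the same set of conditions (needed for paired permutation).
#' @return The validated table (ROI columns in atlas order), invisibly
#'   classed as `thickness_table`.
#' @export
validate_thickness <- function(tab, atlas = dk_atlas(), paired = FALSE) {
  if (!is.data.frame(tab)) stop("thickness table must be a data frame")
  missing_meta <- setdiff(.meta_cols, names(tab))
  if (length(missing_meta))
    stop("missing column(s): ", paste(missing_meta, collapse = ", "))
  roi_cols <- setdiff(names(tab), .meta_cols)
  missing_roi <- setdiff(as.character(atlas), roi_cols)
  if (length(missing_roi))
    stop("missing ROI column(s): ", paste(utils::head(missing_roi, 5), collapse = ", "))
  extra <- setdiff(roi_cols, as.character(atlas))
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  tab <- tab[, c(.meta_cols, as.character(atlas))]
  vals <- as.matrix(tab[, as.character(atlas)])
  if (!is.numeric(vals)) stop("ROI columns must be numeric")
  bad <- which(!is.finite(vals) | vals <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-positive or non-finite thickness at row ", bad[1, 1],
         ", ROI '", as.character(atlas)[bad[1, 2]], "'")
  key <- paste(tab$subject_id, tab$condition, sep = "\r")
  if (anyDuplicated(key) > 0)
    stop("duplicated (subject_id, condition) pair at row ",
         which(duplicated(key))[1])
  if (paired) {
    conds <- sort(unique(tab$condition))
    per_subj <- tapply(tab$condition, tab$subject_id,
                       function(x) identical(sort(unique(x)), conds) &&
                         length(x) == length(conds))
    if (!all(unlist(per_subj)))
      stop("subject(s) not present in all conditions: ",
           paste(names(per_subj)[!unlist(per_subj)], collapse = ", "))
  }
  class(tab) <- c("thickness_table", "data.frame")
  attr(tab, "atlas") <- atlas
  tab
}

#' Read / write ROI thickness tables
#'
#' Tables are delimiter-separated text (TSV or CSV, chosen by extension)
#' with a header row: `subject_id`, `condition`, `group`, then one column
#' per atlas ROI. Columns may appear in any order in the file; they are
#' canonicalized to atlas order on read. Round-trips are lossless at full
#' stored precision (values written with 17 significant digits).
#'
#' @param path file path ending in `.tsv` or `.csv`.
#' @param atlas a [roi_atlas()].
#' @return `read_thickness_table` returns a validated `thickness_table`.
#' @export
read_thickness_table <- function(path, atlas = dk_atlas()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, sep = .delim_for(path), check.names = FALSE,
                    stringsAsFactors = FALSE)
  validate_thickness(tab, atlas)
}

#' @param tab a thickness table (validated on write).
#' @rdname read_thickness_table
#' @export
write_thickness_table <- function(tab, path, atlas = dk_atlas()) {
  tab <- validate_thickness(tab, atlas)
  out <- tab
  for (roi in as.character(atlas)) out[[roi]] <- sprintf("%.17g", tab[[roi]])
  write.table(out, path, sep = .delim_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Binary structural covariance network
#'
#' Wraps a symmetric 0/1 adjacency matrix (zero diagonal) labelled by an
#' atlas.
#'
#' @param adjacency symmetric numeric/integer matrix of 0s and 1s with zero
#'   diagonal, dimensions matching the atlas.
#' @param atlas a [roi_atlas()].
#' @return An object of class `scn_network`.
#' @export
binary_network <- function(adjacency, atlas = dk_atlas()) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != length(atlas) || ncol(adjacency) != length(atlas))
    stop("adjacency dimensions do not match atlas (", length(atlas), " ROIs)")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(as.character(atlas), as.character(atlas))
  structure(list(adjacency = adjacency, atlas = atlas),
            class = "scn_network")
}

#' @export
print.scn_network <- function(x, ...) {
  cat("Binary SCN:", nrow(x$adjacency), "nodes,",
      sum(x$adjacency) / 2, "edges\n")
  invisible(x)
}

#' Read / write binary networks and labelled matrices
#'
#' Networks and covariance matrices are stored as labelled square text
#' tables (ROI labels as header row and first column), TSV or CSV by
#' extension. `read_network` validates symmetry, binarity and the zero
#' diagonal; labels are canonicalized to atlas order.
#'
#' @param net an `scn_network`.
#' @param path file path ending in `.tsv` or `.csv`.
#' @param atlas a [roi_atlas()].
#' @export
write_network <- function(net, path) {
  write_labelled_matrix(net$adjacency, path)
}

#' @rdname write_network
#' @export
read_network <- function(path, atlas = dk_atlas()) {
  m <- read_labelled_matrix(path, atlas)
  binary_network(m, atlas)
}

#' @param m square numeric matrix with identical row and column labels.
#' @rdname write_network
#' @export
write_labelled_matrix <- function(m, path) {
  df <- data.frame(roi = rownames(m),
                   apply(m, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = .delim_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_labelled_matrix <- function(path, atlas = dk_atlas()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = .delim_for(path), check.names = FALSE,
                   stringsAsFactors = FALSE)
  labels <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- labels
  if (!setequal(rownames(m), as.character(atlas)) ||
      !setequal(colnames(m), as.character(atlas)))
    stop("matrix labels do not match atlas")
  m[as.character(atlas), as.character(atlas)]
}
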