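#' ROI atlases
#'
#' An ROI atlas is an ordered set of region labels with a hemisphere tag per
#' region. All thickness tables, covariance matrices and networks in this
#' package are indexed by an atlas, and ROI columns are canonicalized to
#' atlas order on read so that column order never changes a result.
#'
#' @param names character vector of unique region labels, in canonical order.
#' @param hemisphere character vector the same length as `names`, each entry
#'   `"LH"` or `"RH"`.
#' @return An object of class `roi_atlas`: the label vector with a
#'   `hemisphere` attribute.
#' @examples
#' atlas <- roi_atlas(c("lh_a", "rh_a"), c("LH", "RH"))
#' length(atlas)
#' @export
roi_atlas <- function(names, hemisphere) {
  if (!is.character(names) || anyDuplicated(names) > 0)
    stop("atlas names must be a character vector without duplicates")
  if (length(hemisphere) != length(names) ||
      !all(hemisphere %in% c("LH", "RH")))
    stop("hemisphere must be 'LH'/'RH', one per region")
  structure(names, hemisphere = hemisphere, class = "roi_atlas")
}

# The 34 cortical regions per hemisphere of the Desikan-Killiany parcellation,
# in FreeSurfer's conventional order.
.dk_regions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula"
)

#' Desikan-Killiany cortical atlas (68 ROIs)
#'
#' The default parcellation used throughout: 34 cortical regions per
#' hemisphere, labelled `lh_<region>` / `rh_<region>`.
#'
#' @return A `roi_atlas` of length 68 (left hemisphere first).
#' @examples
#' atlas <- dk_atlas()
#' head(atlas)
#' @export
dk_atlas <- function() {
  roi_atlas(c(paste0("lh_", .dk_regions), paste0("rh_", .dk_regions)),
            rep(c("LH", "RH"), each = length(.dk_regions)))
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("ROI atlas:", length(x), "regions (",
      sum(attr(x, "hemisphere") == "LH"), "LH /",
      sum(attr(x, "hemisphere") == "RH"), "RH )\n")
  invisible(x)
}
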