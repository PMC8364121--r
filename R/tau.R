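# Braak-stage tau-PET composite regions of interest.
#
# Neurofibrillary tau pathology spreads in a stereotyped anatomical order
# (Braak staging): entorhinal/hippocampal regions first (stage I-II), then
# limbic and inferolateral temporal cortex (III-IV), finally widespread
# neocortex (V-VI).  Tau-PET uptake is summarised over composite regions
# matching those stages; the temporal meta-ROI (stages I-IV combined) is
# the primary tau measure and is computed as the volume-weighted average
# SUVR of its member regions.

#' Construct an ROI definition
#'
#' @param name Composite name.
#' @param member_region_ids Integer atlas region ids (non-empty).
#' @param stage_tag One of `"I-II"`, `"III-IV"`, `"V-VI"`, `"meta"`.
#' @return A `gmnet_roi` list.
#' @export
roi_definition <- function(name, member_region_ids, stage_tag) {
  if (!length(member_region_ids))
    stop("ROI '", name, "' has no member regions", call. = FALSE)
  stage_tag <- match.arg(stage_tag, c("I-II", "III-IV", "V-VI", "meta"))
  structure(list(name = name,
                 member_region_ids = as.integer(member_region_ids),
                 stage_tag = stage_tag),
            class = "gmnet_roi")
}

#' Volume-weighted composite SUVR
#'
#' Composite tau-PET uptake over a region-of-interest definition:
#' `sum(SUVR_r * vol_r) / sum(vol_r)` over the member regions.  The result
#' always lies between the minimum and maximum member SUVR, and is
#' invariant to rescaling all volumes by a constant.
#'
#' @param region_suvr Named (or id-indexed) numeric vector of per-region
#'   SUVR values; names are region ids.
#' @param region_volume Corresponding region volumes (> 0).
#' @param roi `gmnet_roi` definition.
#' @return The composite SUVR.
#' @examples
#' roi <- roi_definition("demo", c(1, 2), "meta")
#' composite_suvr(c(`1` = 1.2, `2` = 1.8), c(`1` = 2, `2` = 1), roi)  # 1.4
#' @export
composite_suvr <- function(region_suvr, region_volume, roi) {
  ids <- as.character(roi$member_region_ids)
  if (is.null(names(region_suvr))) names(region_suvr) <- seq_along(region_suvr)
  if (is.null(names(region_volume))) names(region_volume) <- seq_along(region_volume)
  missing_s <- setdiff(ids, names(region_suvr))
  missing_v <- setdiff(ids, names(region_volume))
  miss <- union(missing_s, missing_v)
  if (length(miss))
    stop("ROI '", roi$name, "': missing region(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  s <- region_suvr[ids]
  v <- region_volume[ids]
  if (any(!is.finite(v)) || any(v <= 0))
    stop("ROI '", roi$name, "': non-positive region volume", call. = FALSE)
  sum(s * v) / sum(v)
}

#' Braak-stage composite definitions
#'
#' Resolves the four Braak composites — stage I-II (hippocampal
#' formation), stage III-IV (limbic/inferolateral temporal), stage V-VI
#' (widespread neocortex), and the temporal meta-ROI (union of stages
#' I-IV) — against a region table mapping names to atlas ids.  Membership
#' lists are read from a plain-text YAML configuration so that different
#' atlas versions can be supplied; the bundled default matches the
#' package's synthetic 10-region atlas.
#'
#' @param region_table Data frame with columns `region_id` and
#'   `region_name`.
#' @param config_file YAML file with keys `stage_I_II`, `stage_III_IV`,
#'   `stage_V_VI`, each a list of region names.  Defaults to the bundled
#'   synthetic-atlas mapping.
#' @return Named list of four `gmnet_roi` objects
#'   (`braak_I_II`, `braak_III_IV`, `braak_V_VI`, `temporal_meta`).
#' @export
default_braak_definitions <- function(region_table,
                                      config_file = system.file(
                                        "extdata", "braak_synthetic_atlas.yaml",
                                        package = "gmnet")) {
  if (!all(c("region_id", "region_name") %in% names(region_table)))
    stop("'region_table' needs columns region_id and region_name", call. = FALSE)
  cfg <- yaml::read_yaml(config_file)
  need <- c("stage_I_II", "stage_III_IV", "stage_V_VI")
  if (!all(need %in% names(cfg)))
    stop("Braak config must define ", paste(need, collapse = ", "), call. = FALSE)
  resolve <- function(nms) {
    idx <- match(nms, region_table$region_name)
    if (anyNA(idx))
      stop("unresolvable region name(s): ",
           paste(nms[is.na(idx)], collapse = ", "), call. = FALSE)
    region_table$region_id[idx]
  }
  i_ii <- resolve(unlist(cfg$stage_I_II))
  iii_iv <- resolve(unlist(cfg$stage_III_IV))
  v_vi <- resolve(unlist(cfg$stage_V_VI))
  list(
    braak_I_II = roi_definition("braak_I_II", i_ii, "I-II"),
    braak_III_IV = roi_definition("braak_III_IV", iii_iv, "III-IV"),
    braak_V_VI = roi_definition("braak_V_VI", v_vi, "V-VI"),
    temporal_meta = roi_definition("temporal_meta", union(i_ii, iii_iv), "meta")
  )
}

#' Add Braak composite SUVR columns to a subject table
#'
#' @param suvr Matrix or data frame of per-region SUVR (subjects x
#'   regions; column names are region ids).
#' @param volume Matrix of per-region volumes with the same layout, or a
#'   single named vector shared by all subjects.
#' @param definitions List of `gmnet_roi` from
#'   [default_braak_definitions()].
#' @return Data frame with one composite column per definition.
#' @export
braak_composites <- function(suvr, volume, definitions) {
  suvr <- as.matrix(suvr)
  shared_vol <- is.null(dim(volume))
  out <- lapply(definitions, function(roi) {
    vapply(seq_len(nrow(suvr)), function(i) {
      v <- if (shared_vol) volume else {
        vi <- as.matrix(volume)[i, ]
        names(vi) <- colnames(volume)
        vi
      }
      s <- suvr[i, ]
      names(s) <- colnames(suvr)
      composite_suvr(s, v, roi)
    }, numeric(1))
  })
  as.data.frame(out)
}
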