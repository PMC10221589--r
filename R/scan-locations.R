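#' The 11 standardized liver scan-location codes
#'
#' Standardized probe postures used in liver ultrasound screening:
#' SL (substernal longitudinal), ST (substernal transverse), RSPV (right
#' subcostal, portal vein), RSLT (right subcostal, right liver transverse),
#' LD (liver dome), RSHV (right subcostal, hepatic vein), GBL (gallbladder
#' longitudinal), EBL (extrahepatic bile duct longitudinal), RIA / RIP (right
#' intercostal oblique, anterior / posterior), LK (liver-kidney).
#'
#' @return Character vector of the 11 codes, in canonical order.
#' @examples
#' scanLocations()
#' @export
scanLocations <- function() {
  c("SL", "ST", "RSPV", "RSLT", "LD", "RSHV", "GBL", "EBL", "RIA", "RIP", "LK")
}

#' The 8 first-level region-group codes
#'
#' The first hierarchy level classifies 8 regions: ST, RSPV and RSHV (similar
#' right-lobe locations) are merged into one group, SL and EBL (similar
#' features) into another, and the remaining six locations stand alone.
#'
#' @return Character vector of the 8 group codes.
#' @examples
#' regionGroups()
#' @export
regionGroups <- function() {
  c("GROUP_ST_RSPV_RSHV", "GROUP_SL_EBL", "RSLT", "LD", "GBL", "RIA", "RIP",
    "LK")
}

#' Map scan-location labels to first-level region groups
#'
#' The 11-to-8 surjection used by the first hierarchy level: ST/RSPV/RSHV map
#' to \code{GROUP_ST_RSPV_RSHV}, SL/EBL to \code{GROUP_SL_EBL}, every other
#' location to itself.
#'
#' @param label character vector of scan-location codes.
#' @return Character vector of region-group codes, same length.
#' @examples
#' groupLabel(c("ST", "EBL", "LK"))
#' @export
groupLabel <- function(label) {
  bad <- setdiff(label, scanLocations())
  if (length(bad))
    stop("unknown scan-location code(s): ", paste(bad, collapse = ", "))
  out <- label
  out[label %in% c("ST", "RSPV", "RSHV")] <- "GROUP_ST_RSPV_RSHV"
  out[label %in% c("SL", "EBL")] <- "GROUP_SL_EBL"
  out
}

#' Member scan locations of a region group
#'
#' @param group character vector of region-group codes.
#' @return For a single group, the character vector of member scan locations
#'   (its fiber under [groupLabel()]).
#' @export
groupMembers <- function(group) {
  stopifnot(length(group) == 1L, group %in% regionGroups())
  switch(group,
    GROUP_ST_RSPV_RSHV = c("ST", "RSPV", "RSHV"),
    GROUP_SL_EBL = c("SL", "EBL"),
    group)
}
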