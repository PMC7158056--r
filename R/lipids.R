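BRANCH_TYPES <- c("iso", "anteiso", "straight")
ISOMER_CLASSES <- c("isoiso", "isoai", "aiai", "isosc", "aisc", "scsc")

#' Classify an olefin's branch-isomer class from its two chain ends
#'
#' Each end of an olefin carries one branch state (`iso`, `anteiso` or
#' `straight`); the unordered pair gives one of six classes: `isoiso`,
#' `isoai`, `aiai`, `isosc`, `aisc`, `scsc` (e.g. `isoai` is iso-branched
#' at one end and anteiso-branched at the other; `scsc` has no branching
#' at both ends). Symmetric in its arguments.
#'
#' @param end1,end2 Branch state of each end.
#' @return Isomer class string.
#' @examples
#' classify_isomer("iso", "anteiso")      # "isoai"
#' classify_isomer("straight", "straight") # "scsc"
#' @export
classify_isomer <- function(end1, end2) {
  if (!end1 %in% BRANCH_TYPES || !end2 %in% BRANCH_TYPES)
    stop("unknown branch type: ", paste(setdiff(c(end1, end2), BRANCH_TYPES),
                                        collapse = ", "), call. = FALSE)
  pair <- sort(factor(c(end1, end2), levels = BRANCH_TYPES))
  key <- paste(as.character(pair), collapse = "+")
  switch(key,
         "iso+iso" = "isoiso",
         "iso+anteiso" = "isoai",
         "anteiso+anteiso" = "aiai",
         "iso+straight" = "isosc",
         "anteiso+straight" = "aisc",
         "straight+straight" = "scsc")
}

#' Read a GC/MS peak table from CSV
#'
#' Expected header: `analyte_class, chain_length, branch1, branch2, area`
#' (optionally `rt`). `analyte_class` is one of `olefin`, `FAME`,
#' `internal_standard`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_peak_table <- function(path) {
  pk <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("analyte_class", "chain_length", "branch1", "area")
                %in% names(pk)))
  pk
}

#' Quantify a peak table against its internal standard
#'
#' Absolute amounts by direct peak-area comparison with the internal
#' standard (triacontane for olefin extracts, eicosanoic acid for FAMEs),
#' normalized per mL of culture and to a culture density of OD600 = 1:
#' `amount_i = (area_i / area_IS) * amount_IS / volume_mL / od600 /
#' response_i`, with all response factors 1 by default.
#'
#' @param peaks Peak table data.frame (see [read_peak_table()]) containing
#'   exactly one `internal_standard` row with positive area.
#' @param is_spec List with `compound` and `amount_ug` (mass of internal
#'   standard present in the analyzed extract, micrograms).
#' @param ctx List with `culture_volume_mL` and `od600`.
#' @param response Optional named numeric vector of per-analyte response
#'   factors keyed `"<chain_length>:<isomer_class>"`.
#' @return An object of class `lipid_profile`: data.frame `amounts` with
#'   columns `analyte_class`, `chain_length`, `isomer_class`, `amount`
#'   (ug per mL culture per OD unit), plus `meta`.
#' @examples
#' pk <- data.frame(analyte_class = c("olefin", "internal_standard"),
#'                  chain_length = c(29L, 30L),
#'                  branch1 = c("anteiso", NA), branch2 = c("anteiso", NA),
#'                  area = c(1e6, 1e6))
#' pr <- quantify_peaks(pk, list(compound = "triacontane", amount_ug = 40),
#'                      list(culture_volume_mL = 10, od600 = 2))
#' pr$amounts$amount  # 2
#' @export
quantify_peaks <- function(peaks, is_spec, ctx, response = NULL) {
  stopifnot(is.list(is_spec), is_spec$amount_ug > 0,
            ctx$culture_volume_mL > 0, ctx$od600 > 0)
  if (any(peaks$area < 0, na.rm = TRUE))
    stop("negative peak area", call. = FALSE)
  is_row <- which(peaks$analyte_class == "internal_standard")
  if (length(is_row) != 1L)
    stop("peak table must contain exactly one internal_standard row",
         call. = FALSE)
  area_is <- peaks$area[is_row]
  if (is.na(area_is) || area_is <= 0)
    stop("internal standard area must be positive", call. = FALSE)
  an <- peaks[-is_row, , drop = FALSE]
  isomer <- vapply(seq_len(nrow(an)), function(i) {
    if (an$analyte_class[i] == "olefin")
      classify_isomer(an$branch1[i], an$branch2[i])
    else as.character(an$branch1[i])
  }, character(1))
  rf <- rep(1, nrow(an))
  if (!is.null(response)) {
    key <- paste0(an$chain_length, ":", isomer)
    hit <- key %in% names(response)
    rf[hit] <- response[key[hit]]
  }
  amounts <- data.frame(
    analyte_class = an$analyte_class,
    chain_length = an$chain_length,
    isomer_class = isomer,
    amount = (an$area / area_is) * is_spec$amount_ug /
      ctx$culture_volume_mL / ctx$od600 / rf,
    stringsAsFactors = FALSE)
  rownames(amounts) <- NULL
  structure(list(amounts = amounts,
                 meta = list(internal_standard = is_spec, context = ctx)),
            class = "lipid_profile")
}

#' @export
print.lipid_profile <- function(x, ...) {
  cat(sprintf("<lipid_profile> %d analytes, total %.4g ug/mL/OD\n",
              nrow(x$amounts), sum(x$amounts$amount)))
  invisible(x)
}

profile_joint <- function(profile) {
  a <- if (inherits(profile, "lipid_profile")) profile$amounts else profile
  val_col <- intersect(c("amount", "p"), names(a))[1]
  if (is.na(val_col)) stop("profile carries neither amounts nor probabilities")
  tot <- sum(a[[val_col]])
  if (!nrow(a) || tot <= 0)
    stop("empty or zero profile", call. = FALSE)
  agg <- aggregate(setNames(list(a[[val_col]] / tot), "p"),
                   by = list(chain_length = a$chain_length,
                             isomer_class = a$isomer_class), FUN = sum)
  agg[order(agg$chain_length, agg$isomer_class), ]
}

#' Marginal chain-length and isomer-class distributions of a profile
#'
#' @param profile A `lipid_profile` (or a distribution data.frame with
#'   `chain_length`, `isomer_class` and `amount`/`p` columns).
#' @return List with `chain` and `isomer` named probability vectors, each
#'   summing to 1.
#' @export
marginal_distributions <- function(profile) {
  j <- profile_joint(profile)
  chain <- tapply(j$p, j$chain_length, sum)
  chain <- setNames(as.numeric(chain), names(chain))
  isomer <- tapply(j$p, factor(j$isomer_class, levels = ISOMER_CLASSES), sum,
                   default = 0)
  isomer <- setNames(as.numeric(isomer), ISOMER_CLASSES)
  list(chain = chain[order(as.integer(names(chain)))],
       isomer = isomer)
}

#' Compare two olefin profiles
#'
#' Total variation distance on the joint (chain length x isomer class)
#' distribution, the shift of the modal chain length, and per-class isomer
#' share differences (`q` minus `p`).
#'
#' @param p,q Profiles accepted by [marginal_distributions()].
#' @return List with `total_variation`, `modal_chain_shift`
#'   (mode(q) - mode(p)) and `isomer_share_deltas`.
#' @export
compare_profiles <- function(p, q) {
  jp <- profile_joint(p); jq <- profile_joint(q)
  key <- function(j) paste(j$chain_length, j$isomer_class)
  all_keys <- union(key(jp), key(jq))
  vp <- setNames(numeric(length(all_keys)), all_keys)
  vq <- vp
  vp[key(jp)] <- jp$p; vq[key(jq)] <- jq$p
  mp <- marginal_distributions(p); mq <- marginal_distributions(q)
  mode_of <- function(m) as.integer(names(m$chain)[which.max(m$chain)])
  list(total_variation = sum(abs(vp - vq)) / 2,
       modal_chain_shift = mode_of(mq) - mode_of(mp),
       isomer_share_deltas = mq$isomer - mp$isomer)
}
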