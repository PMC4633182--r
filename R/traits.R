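#' @keywords internal
"_PACKAGE"

#' The 22 linear worker measurements
#'
#' Canonical names of the continuous morphometric characters recorded on
#' each worker, all in micrometres: cephalic length (CL), head width behind
#' the eyes (CWb), eye length (EL), frontal carina distance (FRS), mesosoma
#' length (ML), mesosoma width (MW), dorsal petiole node length (NOdL),
#' petiole node height (NOH), petiole node length (NOL), petiole height
#' (PEH), petiole width (PEW), petiole length (PL), postocular distance
#' (PoOC), postpetiole height (PPH), postpetiole length (PPL), postpetiole
#' width (PPW), scape length (SL), propodeal spiracle distance (SPL),
#' spine base distance (SPBA), spiracle-to-spine-tip distance (SPST),
#' spine tip distance (SPTI) and maximum outer spine distance (SPWI).
#'
#' @return Character vector of the 22 trait names in canonical spelling.
#' @export
#' @examples
#' trait_names()
trait_names <- function() {
  c("CL", "CWb", "EL", "FRS", "ML", "MW", "NOdL", "NOH", "NOL", "PEH",
    "PEW", "PL", "PoOC", "PPH", "PPL", "PPW", "SL", "SPL", "SPBA",
    "SPST", "SPTI", "SPWI")
}

# spelling variants that appear in print: PoOc/POC for PoOC, NodL for NOdL.
# matching is case-insensitive on top of this table.
.trait_alias <- c(
  POOC = "PoOC", POC = "PoOC", NODL = "NOdL"
)

#' Normalize trait-name spelling
#'
#' Maps the spelling variants used in print (`PoOc`, `POC`, `NodL`, and any
#' case variant) onto the canonical names of [trait_names()]. Unknown names
#' are returned unchanged.
#'
#' @param x character vector of column or trait names.
#' @return character vector of the same length with canonical trait names.
#' @export
#' @examples
#' canonical_trait(c("PoOc", "NodL", "spst", "species"))
canonical_trait <- function(x) {
  up <- toupper(x)
  canon <- trait_names()
  out <- x
  hit <- match(up, toupper(canon))
  out[!is.na(hit)] <- canon[hit[!is.na(hit)]]
  ali <- match(up, names(.trait_alias))
  out[!is.na(ali)] <- unname(.trait_alias[ali[!is.na(ali)]])
  out
}

#' Validate a table of trait measurements
#'
#' Checks positivity, the plausibility window, and the ordering relations a
#' worker's measurements must satisfy: `PoOC < CL`, `NOH <= PEH` and
#' `SPBA < SPWI` (the minimum spine-base distance is below the maximum
#' outer spine distance).
#'
#' @param traits data frame or named numeric vector holding the 22 traits
#'   (micrometres).
#' @param window numeric length-2 plausibility window in micrometres;
#'   `NULL` disables the window check. The default lower bound admits the
#'   short waist measurements (NOH, SPL) that fall below 100 um.
#' @param strict if `TRUE` (default) violations raise an error naming the
#'   offending field; otherwise a character vector of messages is returned
#'   (length zero when valid).
#' @return Invisibly `TRUE` when valid (strict mode), else the messages.
#' @export
validate_traits <- function(traits, window = c(40, 2000), strict = TRUE) {
  if (is.numeric(traits)) traits <- as.data.frame(as.list(traits))
  need <- trait_names()
  miss <- setdiff(need, names(traits))
  msgs <- character(0)
  if (length(miss)) {
    msgs <- c(msgs, paste0("missing trait field(s): ", paste(miss, collapse = ", ")))
    if (strict) stop(msgs, call. = FALSE) else return(msgs)
  }
  for (tn in need) {
    v <- traits[[tn]]
    if (any(!is.finite(v)))
      msgs <- c(msgs, paste0(tn, ": non-finite value"))
    else if (any(v <= 0))
      msgs <- c(msgs, paste0(tn, ": non-positive value"))
    else if (!is.null(window) && any(v < window[1] | v > window[2]))
      msgs <- c(msgs, paste0(tn, ": outside plausibility window [",
                             window[1], ", ", window[2], "] um"))
  }
  ord <- function(ok, lab) if (any(!ok, na.rm = TRUE)) paste0("ordering violated: ", lab)
  msgs <- c(msgs,
            ord(traits$PoOC < traits$CL,  "PoOC < CL"),
            ord(traits$NOH <= traits$PEH, "NOH <= PEH"),
            ord(traits$SPBA < traits$SPWI, "SPBA < SPWI"))
  msgs <- msgs[!vapply(msgs, is.null, logical(1))]
  if (length(msgs) && strict) stop(paste(msgs, collapse = "; "), call. = FALSE)
  if (strict) invisible(TRUE) else msgs
}

#' Cephalic size
#'
#' Cephalic size CS is the arithmetic mean of cephalic length (CL) and head
#' width behind the eyes (CWb); it is the body-size denominator of most
#' shape ratios in the group.
#'
#' @param traits named list/vector/data frame containing `CL` and `CWb`
#'   in micrometres.
#' @return CS in micrometres (vectorized over rows).
#' @export
#' @examples
#' compute_cs(c(CL = 600, CWb = 500))   # 550
compute_cs <- function(traits) {
  if (is.numeric(traits)) traits <- as.list(traits)
  for (f in c("CL", "CWb")) {
    if (is.null(traits[[f]]) || any(is.na(traits[[f]])))
      stop("compute_cs: missing trait field '", f, "'", call. = FALSE)
    if (any(traits[[f]] <= 0))
      stop("compute_cs: non-positive '", f, "'", call. = FALSE)
  }
  (traits$CL + traits$CWb) / 2
}

#' Ratio families used by the key and the diagnoses
#'
#' All trait/CS ratios plus the handful of trait/trait ratios the key and
#' differential diagnoses use.
#'
#' @return character vector of known ratio names, e.g. `"SPST/CS"`,
#'   `"CL/CWb"`, `"PoOC/NOH"`, `"FRS/SL"`.
#' @export
known_ratios <- function() {
  over_cs <- setdiff(trait_names(), c("CL", "CWb"))
  c(paste0(over_cs, "/CS"), "CL/CS", "CWb/CS",
    "CL/CWb", "PoOC/CL", "SPST/CL", "SPBA/CWb", "PoOC/NOH", "FRS/SL")
}

#' Compute named shape ratios
#'
#' Computes the requested dimensionless ratios from a table of raw
#' measurements; `CS` (micrometres) is always included as the first column.
#' A ratio name is `"A/B"` where `A` is a trait and `B` is a trait or `CS`.
#'
#' @param traits data frame (or named vector) of trait values in
#'   micrometres.
#' @param ratios character vector of ratio names; default is every ratio in
#'   [known_ratios()]. An empty vector yields `CS` only.
#' @return data frame with column `CS` plus one column per requested ratio.
#' @export
#' @examples
#' compute_ratios(c(CL = 600, CWb = 500), "CL/CWb")$`CL/CWb`  # 1.2
compute_ratios <- function(traits, ratios = known_ratios()) {
  if (is.numeric(traits)) traits <- as.data.frame(as.list(traits))
  cs <- compute_cs(traits)
  out <- data.frame(CS = cs, check.names = FALSE)
  if (!length(ratios)) return(out)
  unknown <- setdiff(ratios, known_ratios())
  if (length(unknown))
    stop("unknown ratio name(s): ", paste(unknown, collapse = ", "),
         "; known ratios are: ", paste(known_ratios(), collapse = ", "),
         call. = FALSE)
  get_part <- function(p) if (p == "CS") cs else {
    v <- traits[[p]]
    if (is.null(v)) stop("trait '", p, "' required for a requested ratio is absent",
                         call. = FALSE)
    v
  }
  for (r in ratios) {
    parts <- strsplit(r, "/", fixed = TRUE)[[1]]
    den <- get_part(parts[2])
    if (any(den == 0)) stop("zero denominator in ratio ", r, call. = FALSE)
    out[[r]] <- get_part(parts[1]) / den
  }
  out
}
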