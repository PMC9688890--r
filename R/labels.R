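#' Thalamic nucleus labels
#'
#' The intrinsic thalamic network uses the standard 25-nuclei-per-hemisphere
#' parcellation (FreeSurfer `segmentThalamicNuclei` scheme), giving 50 regions
#' in total. Labels render as `"<Hemisphere>-<code>"`, e.g. `"Left-AV"` or
#' `"Right-PuM"`; note that the suprageniculate/limitans code `L-Sg` itself
#' contains a hyphen, so parsing splits on the first hyphen only.
#'
#' @name nucleus-labels
NULL

# 25 nucleus codes per hemisphere, fixed order used throughout the package
.thal_codes <- c(
  "AV",                                       # anterior
  "LD", "LP",                                 # lateral
  "VA", "VAmc", "VLa", "VLp", "VPL", "VM",    # ventral
  "CeM", "CL", "Pc", "CM", "Pf",              # intralaminar
  "Pt", "MV", "MDm", "MDl",                   # medial
  "LGN", "MGN", "L-Sg", "PuA", "PuM", "PuL", "PuI"  # posterior
)

.thal_long_names <- c(
  AV = "Anteroventral", LD = "Laterodorsal", LP = "Lateral posterior",
  VA = "Ventral anterior", VAmc = "Ventral anterior magnocellular",
  VLa = "Ventral lateral anterior", VLp = "Ventral lateral posterior",
  VPL = "Ventral posterolateral", VM = "Ventromedial",
  CeM = "Central medial", CL = "Central lateral", Pc = "Paracentral",
  CM = "Centromedian", Pf = "Parafascicular", Pt = "Paratenial",
  MV = "Medial ventral", MDm = "Mediodorsal medial magnocellular",
  MDl = "Mediodorsal lateral parvocellular", LGN = "Lateral geniculate",
  MGN = "Medial geniculate", `L-Sg` = "Suprageniculate",
  PuA = "Pulvinar anterior", PuM = "Pulvinar medial",
  PuL = "Pulvinar lateral", PuI = "Pulvinar inferior"
)

# anatomical group of each code, used for Table-style layouts and as the
# default correlation-block assignment of the synthetic generator
.thal_groups <- c(
  AV = "anterior",
  LD = "lateral", LP = "lateral",
  VA = "ventral", VAmc = "ventral", VLa = "ventral", VLp = "ventral",
  VPL = "ventral", VM = "ventral",
  CeM = "intralaminar", CL = "intralaminar", Pc = "intralaminar",
  CM = "intralaminar", Pf = "intralaminar",
  Pt = "medial", MV = "medial", MDm = "medial", MDl = "medial",
  LGN = "posterior", MGN = "posterior", `L-Sg` = "posterior",
  PuA = "posterior", PuM = "posterior", PuL = "posterior", PuI = "posterior"
)

#' All 50 nucleus labels in canonical order
#'
#' Left hemisphere first, then right, each in the fixed anatomical code order.
#'
#' @return Character vector of length 50, e.g. `"Left-AV"`, ..., `"Right-PuI"`.
#' @export
#' @examples
#' head(thalamic_nucleus_labels())
thalamic_nucleus_labels <- function() {
  c(paste0("Left-", .thal_codes), paste0("Right-", .thal_codes))
}

#' Nucleus label metadata table
#'
#' @return Data frame with columns `label`, `hemisphere`, `code`, `long_name`,
#'   and `anatomical_group` for all 50 nuclei.
#' @export
nucleus_label_table <- function() {
  labs <- thalamic_nucleus_labels()
  hemi <- rep(c("Left", "Right"), each = length(.thal_codes))
  code <- rep(.thal_codes, 2)
  data.frame(
    label = labs, hemisphere = hemi, code = code,
    long_name = unname(.thal_long_names[code]),
    anatomical_group = unname(.thal_groups[code]),
    stringsAsFactors = FALSE
  )
}

#' Parse a nucleus label
#'
#' @param x character vector of rendered labels such as `"Left-AV"`.
#' @return Data frame with columns `hemisphere` and `code`; errors on labels
#'   that do not parse to a known hemisphere/code pair.
#' @export
parse_nucleus_label <- function(x) {
  m <- regmatches(x, regexec("^(Left|Right)-(.+)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("not a nucleus label: ", paste(x[bad], collapse = ", "))
  }
  hemi <- vapply(m, `[`, "", 2L)
  code <- vapply(m, `[`, "", 3L)
  unknown <- !code %in% .thal_codes
  if (any(unknown)) {
    stop("unknown nucleus code: ", paste(code[unknown], collapse = ", "))
  }
  data.frame(hemisphere = hemi, code = code, stringsAsFactors = FALSE)
}

# Accepted aliases for nucleus column names: the FreeSurfer
# segmentThalamicNuclei long forms and the MV(Re)/reuniens variants all map
# onto the short codes used here.
.code_aliases <- local({
  al <- c(
    "MV(Re)" = "MV", "MV-(Re)" = "MV", "Re" = "MV",
    "Reuniens (medial ventral)" = "MV",
    "Limitans (suprageniculate)" = "L-Sg", "Sg" = "L-Sg",
    "Pul" = "PuI"
  )
  c(al, stats::setNames(names(.thal_long_names), .thal_long_names))
})

#' Canonicalize nucleus column names
#'
#' Maps `"Left-AV"`-style names and documented aliases (FreeSurfer long names,
#' `MV(Re)`, `Limitans (suprageniculate)`, ...) to canonical labels. Names that
#' are not nucleus columns are returned unchanged.
#'
#' @param x character vector of column names.
#' @return character vector of the same length.
#' @export
canonical_nucleus_name <- function(x) {
  vapply(x, function(nm) {
    m <- regmatches(nm, regexec("^(Left|Right|Lt\\.?|Rt\\.?)[-. ](.+)$", nm))[[1]]
    if (length(m) != 3L) return(nm)
    hemi <- c(Left = "Left", Right = "Right", Lt = "Left", `Lt.` = "Left",
              Rt = "Right", `Rt.` = "Right")[[m[2]]]
    code <- m[3]
    if (!code %in% .thal_codes) {
      hit <- which(tolower(names(.code_aliases)) == tolower(code))
      if (length(hit) == 0L) return(nm)
      code <- .code_aliases[[hit[1L]]]
    }
    paste0(hemi, "-", code)
  }, "", USE.NAMES = FALSE)
}
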