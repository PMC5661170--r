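#' The 90-region cerebral parcellation table
#'
#' Region codes for the standard 90-region automated anatomical labelling
#' (AAL) cerebral parcellation used as network nodes: 45 homologous regions
#' per hemisphere, numbered in the conventional interleaved order (odd
#' indices left, even indices right).
#'
#' @return A data.frame with columns `index` (1..90), `code` (abbreviation
#'   with `.L`/`.R` hemisphere suffix, e.g. `"THA.L"`), and `hemisphere`
#'   (`"L"` or `"R"`).
#' @examples
#' head(aal90_regions())
#' subset(aal90_regions(), code %in% c("THA.L", "PoCG.L"))
#' @export
aal90_regions <- function() {
  base <- c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "DCG", "PCG", "HIP", "PHG", "AMYG", "CAL", "CUN", "LING",
    "SOG", "MOG", "IOG", "FFG", "PoCG", "SPG", "IPL", "SMG", "ANG",
    "PCUN", "PCL", "CAU", "PUT", "PAL", "THA", "HES", "STG", "TPOsup",
    "MTG", "TPOmid", "ITG"
  )
  hemi <- rep(c("L", "R"), times = 45)
  code <- paste(rep(base, each = 2), hemi, sep = ".")
  data.frame(index = 1:90, code = code, hemisphere = hemi,
             stringsAsFactors = FALSE)
}

# Resolve region codes to atlas indices, with validation.
region_index <- function(codes) {
  tab <- aal90_regions()
  idx <- match(codes, tab$code)
  if (anyNA(idx)) {
    stop("unknown region code(s): ",
         paste(codes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}
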