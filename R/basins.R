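# Basin conventions shared by the first-passage, switching-time and
# sorting machinery.  Basins are protein-count half-planes split at the
# saddle of the adiabatically reduced drift; because the reduced drift
# depends on the gene rates only through the locked ratios dG/kG and
# dG/kG0, the split is invariant along a kappa family.  The sorting
# experiment instead uses its fixed cytometry threshold (400 by default).

#' Basin split and metastable points
#'
#' `basinThreshold` returns the protein coordinate of the reduced-drift
#' saddle (floored to an integer): states with `n > threshold` form the
#' "on" basin, the rest the "off" basin.  `metastablePoints` returns the
#' representative microstates the switching machinery starts from: in the
#' slow regime (kappa < 0.01) the per-layer fixed points with the gene
#' state set accordingly (closed at the origin, open at the expressed
#' state); otherwise the stable points of the reduced drift, with the
#' gene closed at the off state and open at the on state.
#'
#' @param params parameter set
#' @return `basinThreshold`: integer protein count; `metastablePoints`:
#'   list with integer vectors `off` and `on`, each `c(alpha, m, n)`
#' @export
basinThreshold <- function(params) {
  cp <- findCriticalPoints(params)
  sad <- cp[cp$type == "saddle", ]
  if (nrow(sad) == 0)
    stop("reduced drift has no saddle; supply an explicit threshold")
  as.integer(floor(sad$n[1]))
}

#' @rdname basinThreshold
#' @export
metastablePoints <- function(params) {
  if (kappa(params) < 0.01) {
    fp <- layerFixedPoint(1, params)
    list(off = c(alpha = 0L, m = 0L, n = 0L),
         on = c(alpha = 1L, m = as.integer(round(fp["m"])),
                n = as.integer(round(fp["n"]))))
  } else {
    cp <- findCriticalPoints(params)
    st <- cp[cp$type == "stable", ]
    if (nrow(st) < 2) {  # monostable reduced drift: fall back to layers
      fp <- layerFixedPoint(1, params)
      return(list(off = c(alpha = 0L, m = 0L, n = 0L),
                  on = c(alpha = 1L, m = as.integer(round(fp["m"])),
                         n = as.integer(round(fp["n"])))))
    }
    st <- st[order(st$n), ]
    list(off = c(alpha = 0L, m = as.integer(round(st$m[1])),
                 n = as.integer(round(st$n[1]))),
         on = c(alpha = 1L, m = as.integer(round(st$m[2])),
                n = as.integer(round(st$n[2]))))
  }
}
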