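# TINA mixing-recipe calculator: from a designed relative distribution to
# per-tRNA stock-mix concentrations and pipetting volumes for PUREdeltatRNA
# reactions.

#' TINA recipe specification
#'
#' Defaults follow the standard PUREdeltatRNA workflow: 200 uM total
#' elongator tRNA plus 10 uM initiator in the reaction, delivered by adding
#' 1 ul of a 5x concentrated tRNA stock mix to a 5 ul reaction, with each
#' synthetic tRNA resuspended to a 100 uM source stock.
#'
#' @param distribution elongator [TRNADistribution-class].
#' @param totalElongatorConc total elongator tRNA in the reaction, uM.
#' @param initiatorConc initiator tRNA final concentration, uM.
#' @param stockConc source stock concentration, uM; scalar or named per tRNA.
#' @param stockMixFold fold-concentration of the stock mix.
#' @param reactionVolume final reaction volume, ul.
#' @param stockMixVolumeAdded stock-mix volume added per reaction, ul.
#' @param minPipettableVolume volumes below this are flagged infeasible, ul.
#' @return A [RecipeSpec-class].
#' @export
RecipeSpec <- function(distribution, totalElongatorConc = 200,
                       initiatorConc = 10, stockConc = 100,
                       stockMixFold = 5, reactionVolume = 5,
                       stockMixVolumeAdded = 1, minPipettableVolume = 0.5) {
  new("RecipeSpec", distribution = distribution,
      totalElongatorConc = totalElongatorConc, initiatorConc = initiatorConc,
      stockConc = as.numeric(stockConc), stockMixFold = stockMixFold,
      reactionVolume = reactionVolume,
      stockMixVolumeAdded = stockMixVolumeAdded,
      minPipettableVolume = minPipettableVolume)
}

#' Compute a TINA mixing recipe
#'
#' For each elongator tRNA: final reaction concentration
#' `abundance * totalElongatorConc`; concentration in the fold-concentrated
#' stock mix `stockMixFold * final`; volume of source stock to combine into a
#' `mixVolume` ul stock mix `mixConc * mixVolume / stockConc`. The initiator
#' tRNA is handled identically at its fixed final concentration. Volumes are
#' reported at full precision plus a column rounded to `pipetteResolution`;
#' a per-tRNA `pipettable` flag marks volumes below the minimum pipettable
#' volume (suggesting an intermediate dilution — never silently rounded), and
#' `reachable` marks tRNA whose stock-mix concentration exceeds the source
#' stock (unreachable by dilution).
#'
#' @param spec a [RecipeSpec-class].
#' @param mixVolume total stock-mix volume to prepare, ul.
#' @param pipetteResolution rounding step for the convenience column, ul.
#' @return A [Recipe-class].
#' @examples
#' d <- uniformDistribution(paste0("t", 1:20))
#' recipeTable(computeRecipe(RecipeSpec(d), mixVolume = 20))
#' @export
computeRecipe <- function(spec, mixVolume = 20, pipetteResolution = 0.1) {
  stopifnot(is(spec, "RecipeSpec"), mixVolume > 0)
  d <- spec@distribution
  trna <- c(d@trna, "initiator")
  finalConc <- c(abundances(d) * spec@totalElongatorConc, spec@initiatorConc)
  stock <- if (length(spec@stockConc) == 1) rep(spec@stockConc, length(trna))
           else {
    if (is.null(names(spec@stockConc)) || !all(trna %in% names(spec@stockConc)))
      stop("per-tRNA stockConc must be named and cover all tRNA + initiator")
    as.numeric(spec@stockConc[trna])
  }
  mixConc <- spec@stockMixFold * finalConc
  vol <- mixConc * mixVolume / stock
  reachable <- mixConc <= stock + 1e-12
  pipettable <- vol >= spec@minPipettableVolume | vol == 0
  tab <- data.frame(
    trna = trna,
    role = c(rep("elongator", length(d@trna)), "initiator"),
    final_conc_uM = unname(finalConc),
    stock_mix_conc_uM = unname(mixConc),
    stock_volume_ul = unname(vol),
    stock_volume_rounded_ul = round(unname(vol) / pipetteResolution) *
      pipetteResolution,
    reachable = unname(reachable),
    pipettable = unname(pipettable),
    stringsAsFactors = FALSE)
  if (any(!reachable))
    warning("stock-mix concentration exceeds source stock for: ",
            paste(trna[!reachable], collapse = ", "))
  new("Recipe", table = tab, mixVolume = mixVolume, spec = spec,
      feasible = all(reachable) && all(pipettable))
}

#' Re-simulate mixing a recipe and recover the distribution
#'
#' Combines the recipe's source-stock volumes at their stock concentrations
#' into the stated mix volume and renormalizes the resulting elongator
#' concentrations — the round-trip check that a recipe reproduces its
#' specified distribution.
#'
#' @param recipe a [Recipe-class].
#' @param rounded use the pipette-rounded volumes instead of full precision
#'   (to quantify the composition error introduced by rounding).
#' @return A [TRNADistribution-class].
#' @export
remixRecipe <- function(recipe, rounded = FALSE) {
  tab <- recipe@table[recipe@table$role == "elongator", ]
  vol <- if (rounded) tab$stock_volume_rounded_ul else tab$stock_volume_ul
  stockConc <- recipe@spec@stockConc
  stock <- if (length(stockConc) == 1) rep(stockConc, nrow(tab))
           else as.numeric(stockConc[tab$trna])
  mixConc <- vol * stock / recipe@mixVolume
  TRNADistribution(tab$trna, mixConc, normalize = TRUE)
}
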