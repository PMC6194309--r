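#' Restrict a dataset to a subset of units
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param ids unit ids to keep (order is irrelevant; neurogram assembly
#'   re-orders by CF).
#' @return a \linkS4class{SpikeDataset} with only those units.
#' @export
subsetUnits <- function(dataset, ids) {
  ids <- as.character(ids)
  missing <- setdiff(ids, unitIds(dataset))
  if (length(missing)) stop("unknown unit(s): ", paste(missing, collapse = ", "))
  u <- unitMeta(dataset)
  SpikeDataset(design(dataset), u[match(ids, u$unit_id), , drop = FALSE],
               dataset@spikes[ids])
}

## Empty nested spike list for a design: units -> tokens -> repetitions.
.emptySpikeList <- function(unitIds, design) {
  toks <- tokenLabels(design)
  R <- design@nRepetitions
  one <- setNames(
    lapply(toks, function(tok) rep(list(numeric(0)), R)), toks)
  setNames(lapply(unitIds, function(u) one), unitIds)
}
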