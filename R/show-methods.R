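#' @describeIn HomologyPattern-class compact display
#' @param object object to display.
setMethod("show", "HomologyPattern", function(object) {
  cat("HomologyPattern ", patternName(object),
      " (periodicity ", object@unitLen + object@spacerLen,
      ", region ", object@regionLen, " bp", sep = "")
  if (object@endPolicy == "extend" && object@extendBy > 0) {
    cat(", last unit extended by ", object@extendBy, " bp", sep = "")
  }
  cat(")\n")
  n <- length(homologousPositions(object))
  cat("  ", n, " homologous positions (",
      round(100 * n / object@regionLen, 1), "% identity)\n", sep = "")
})

#' @describeIn Cassette-class compact display
#' @param object object to display.
setMethod("show", "Cassette", function(object) {
  L <- length(object@homologyMask)
  runs <- .maskRuns(object@homologyMask)
  cat("Cassette '", object@id, "': ", L, " bp, ",
      sum(object@homologyMask), " homologous positions (",
      round(100 * mean(object@homologyMask), 1), "%) in ",
      nrow(runs), " run(s)\n", sep = "")
})

#' @describeIn TripletCensus-class compact display
#' @param object object to display.
setMethod("show", "TripletCensus", function(object) {
  cat("TripletCensus: ", censusTotal(object), " triplet(s) in ",
      object@unitCount, " homologous run(s)\n", sep = "")
  top <- utils::head(censusTable(object), 5)
  if (nrow(top)) {
    cat("  top classes:",
        paste(sprintf("%s=%d", top$triplet, top$count), collapse = ", "),
        "\n")
  }
})

#' @describeIn MutationCallSet-class compact display
#' @param object object to display.
setMethod("show", "MutationCallSet", function(object) {
  cat("MutationCallSet '", object@sporeId, "': ", nCT(object), " C>T, ",
      nGA(object), " G>A, ", nOther(object), " other over ",
      object@refLength, " bp\n", sep = "")
})

#' @describeIn SiteProfile-class compact display
#' @param object object to display.
setMethod("show", "SiteProfile", function(object) {
  cat("SiteProfile",
      if (nzchar(object@construct)) paste0(" '", object@construct, "'"),
      ": ", length(object@siteCounts), " sites, ", object@nSpores,
      " spores, peak ", round(max(sitePercent(object)), 2), "% at position ",
      which.max(object@siteCounts), "\n", sep = "")
})

#' @describeIn RipSimModel-class compact display
#' @param object object to display.
setMethod("show", "RipSimModel", function(object) {
  cat("RipSimModel: lambda = ", object@lambdaMean,
      ", escape = ", object@escapeProb,
      ", C>T fraction = ", object@ctGaRatio,
      ", indel rate = ", object@indelRate,
      if (length(object@spatialProfile)) ", custom spatial profile"
      else ", triangular spatial profile",
      "\n", sep = "")
})
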