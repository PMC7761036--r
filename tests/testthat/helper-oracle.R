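# Independent brute-force allocator: resolves every linkage one at a time
# straight from the allocation rule text, with no matrix bookkeeping and no
# pass structure. Demand-set linkages in the default table are exclusive to
# their class, so their allocation equals their profile amount and each
# linkage can be resolved independently.
oracle_allocate <- function(amounts, table = default_assignment_table(),
                            fraction = "AIR") {
  classes <- table$classes
  ov <- table$overrides[table$overrides$fraction == fraction, , drop = FALSE]
  for (i in seq_len(nrow(ov))) {
    classes[[ov$class[i]]] <- setdiff(classes[[ov$class[i]]], ov$linkage[i])
  }
  res <- stats::setNames(rep(0, length(classes) + 1),
                         c(names(classes), "UA"))
  get <- function(lk) if (lk %in% names(amounts)) amounts[[lk]] else 0
  demand_of <- function(cl) {
    ds <- table$rules$demand_sets[[cl]]
    if (is.null(ds)) return(0)
    total <- 0
    for (entry in ds) {
      w <- 1
      if (grepl("\\*", entry)) {
        w <- as.numeric(sub("\\*.*", "", entry))
        entry <- sub(".*\\*", "", entry)
      }
      # demand counts only what the class actually received; default-table
      # demand linkages are exclusive, so that is the full amount when the
      # linkage (still) belongs to the class
      if (entry %in% classes[[cl]]) total <- total + w * get(entry)
    }
    total
  }
  for (lk in names(amounts)) {
    a <- amounts[[lk]]
    cand <- names(classes)[vapply(classes, function(v) lk %in% v, logical(1))]
    if (length(cand) == 0) {
      res[["UA"]] <- res[["UA"]] + a
    } else if (length(cand) == 1) {
      res[[cand]] <- res[[cand]] + a
    } else if (lk == "4-GalAp" && all(c("RG-I", "HG") %in% cand)) {
      r <- min(a, get("2-Rhap") + get("2,4-Rhap"))
      res[["RG-I"]] <- res[["RG-I"]] + r
      res[["HG"]] <- res[["HG"]] + (a - r)
    } else if (lk == "4-Glcp") {
      pool <- a
      if ("XG" %in% cand) {
        t1 <- min(pool, get("4,6-Glcp") * table$rules$xg_unbranched_ratio)
        res[["XG"]] <- res[["XG"]] + t1
        pool <- pool - t1
      }
      if ("HM" %in% cand) {
        t2 <- min(pool, get("4-Manp") * table$rules$glc_man_ratio)
        res[["HM"]] <- res[["HM"]] + t2
        pool <- pool - t2
      }
      sink <- if ("CE" %in% cand) "CE" else if ("XG" %in% cand) "XG"
              else if ("HM" %in% cand) "HM" else "UA"
      res[[sink]] <- res[[sink]] + pool
    } else {
      d <- vapply(cand, demand_of, numeric(1))
      if (sum(d) > 0) {
        for (cl in cand) res[[cl]] <- res[[cl]] + a * d[[cl]] / sum(d)
      } else {
        row_order <- c("AB", "AG-I", "AG-II/ET", "HX", "XG", "CE", "CA",
                       "RG-I", "HG", "HM")
        first <- intersect(row_order, cand)[1]
        if (is.na(first)) first <- cand[1]
        res[[first]] <- res[[first]] + a
      }
    }
  }
  res
}
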