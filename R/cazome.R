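#' CAZyme family count tables (CAZomes)
#'
#' A CAZome table records, per bacterial genome, the number of genes in
#' each carbohydrate-active enzyme (CAZy) family — glycoside hydrolases
#' (GH), polysaccharide lyases (PL) and carbohydrate esterases (CE) —
#' with each family placed in a functional category (cellulose/pectin-
#' active, cell wall elongation, debranching, oligosaccharide-degrading,
#' polysaccharide lyases, carbohydrate esterases). The long format is
#' compatible with tabulated dbCAN annotation counts.
#'
#' A family id may legitimately appear under two categories when the
#' source table lists it twice (GH27 sits in both the debranching and the
#' oligosaccharide-degrading sections of the built-in table); the
#' duplicate rows are kept — both contribute to their category totals —
#' and a warning notes the duplication.
#'
#' @param counts data.frame with columns `family`, `category`, `genome`,
#'   `count` and optionally `activity` (free-text major known activity).
#' @return a `cazome_table` tibble.
#' @export
cazome_table <- function(counts) {
  stopifnot(is.data.frame(counts))
  need <- c("family", "category", "genome", "count")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols) > 0) {
    stop("counts are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(counts)
  if (!"activity" %in% names(out)) out$activity <- NA_character_
  if (any(is.na(out$count)) || any(out$count < 0) ||
      any(out$count != round(out$count))) {
    stop("CAZy family counts must be non-negative integers", call. = FALSE)
  }
  out$count <- as.integer(out$count)
  # one category per family within a table, except printed double listings
  fam_cat <- unique(out[, c("family", "category")])
  dup <- unique(fam_cat$family[duplicated(fam_cat$family)])
  if (length(dup) > 0) {
    warning("family id(s) listed in more than one category (kept as ",
            "printed; both rows count toward their category totals): ",
            paste(dup, collapse = ", "), call. = FALSE)
  }
  key <- paste(out$family, out$category, out$genome)
  if (anyDuplicated(key)) {
    stop("duplicated family x category x genome rows", call. = FALSE)
  }
  attr(out, "duplicated_families") <- dup
  class(out) <- c("cazome_table", class(out))
  out
}

#' Read a CAZome table from TSV
#'
#' Accepts the long format `family, activity, category, genome, count`
#' (one row per family x genome) or a wide matrix with a `family` column,
#' optional `activity`/`category` columns, and one column per genome.
#'
#' @param path TSV file path.
#' @param category for wide files lacking a `category` column, a single
#'   category label to assign to all families.
#' @return a [cazome_table()].
#' @export
read_cazome <- function(path, category = NULL) {
  if (!file.exists(path)) stop("CAZome table not found: ", path,
                               call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "")
  if (all(c("genome", "count") %in% names(raw))) {
    return(cazome_table(raw))
  }
  if (!"family" %in% names(raw)) {
    stop("CAZome table needs either long columns (family, category, ",
         "genome, count) or a wide layout with a 'family' column",
         call. = FALSE)
  }
  meta_cols <- intersect(c("family", "activity", "category"), names(raw))
  genome_cols <- setdiff(names(raw), meta_cols)
  if (length(genome_cols) == 0) stop("no genome columns found", call. = FALSE)
  long <- do.call(rbind, lapply(genome_cols, function(g) {
    data.frame(
      family = raw$family,
      activity = if ("activity" %in% meta_cols) raw$activity else NA_character_,
      category = if ("category" %in% meta_cols) raw$category
                 else category %||% stop("wide table lacks a 'category' ",
                                         "column and no category was given",
                                         call. = FALSE),
      genome = g,
      count = raw[[g]],
      stringsAsFactors = FALSE
    )
  }))
  cazome_table(long)
}

#' CAZomes of the canola-meal Bacteroides isolates
#'
#' The built-in count table for the six genome-sequenced canola-meal
#' isolates (B. thetaiotaomicron CMU13/CMU108, B. ovatus CMU19/CMU33,
#' B. fragilis CMU36/CMU103) and the two environmental reference strains
#' (B. theta VPI-5482, B. ovatus ATCC8483): the major GH families in four
#' functional categories plus the PL and CE families, as published.
#' Cells highlighted in the source (isolate count exceeding its
#' reference strain's) carry `highlighted = 1` for the bolded entries.
#'
#' @return a [cazome_table()] with an extra `highlighted` column.
#' @export
canola_cazome <- function() {
  counts_path <- system.file("extdata", "cazome_bacteroides_counts.tsv",
                             package = "glycolinker", mustWork = TRUE)
  tab <- suppressWarnings(read_cazome(counts_path))
  hi_path <- system.file("extdata", "cazome_bacteroides_highlighted.tsv",
                         package = "glycolinker", mustWork = TRUE)
  hi <- utils::read.table(hi_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  key <- paste(tab$family, tab$category, tab$genome)
  tab$highlighted <- as.integer(key %in% paste(hi$family, hi$category,
                                               hi$genome))
  tab
}

#' Reference pairing of canola-meal isolates to wild-type strains
#'
#' @return named character vector mapping each high-efficiency isolate to
#'   its species' environmental reference genome.
#' @export
canola_reference_pairs <- function() {
  c(CMU13 = "VPI-5482", CMU108 = "VPI-5482",
    CMU19 = "ATCC8483", CMU33 = "ATCC8483")
}

#' Aggregate a CAZome into category totals
#'
#' Sums family counts within each functional category for every genome,
#' and reports each genome's grand total over all categories in the
#' table. A family printed under two categories contributes to both its
#' category totals (and twice to the grand total, matching the printed
#' table's arithmetic).
#'
#' @param table a [cazome_table()].
#' @return a tibble `category, genome, total`, with `category = "Total"`
#'   rows holding the per-genome grand totals.
#' @export
aggregate_cazome <- function(table) {
  stopifnot(inherits(table, "cazome_table"))
  agg <- stats::aggregate(count ~ category + genome, data = table, FUN = sum)
  grand <- stats::aggregate(count ~ genome, data = agg, FUN = sum)
  grand$category <- "Total"
  out <- rbind(agg[, c("category", "genome", "count")],
               grand[, c("category", "genome", "count")])
  names(out)[names(out) == "count"] <- "total"
  cats <- unique(table$category)
  out <- out[order(match(out$category, c(cats, "Total")), out$genome), ]
  rownames(out) <- NULL
  tibble::as_tibble(out)
}

#' Flag CAZy families enriched in isolates over reference strains
#'
#' A family is flagged for an isolate when the isolate's gene count is
#' strictly greater than its paired reference genome's count ("more
#' members" — equality is not enrichment).
#'
#' @param table a [cazome_table()].
#' @param pairs named character vector `isolate -> reference genome`,
#'   e.g. [canola_reference_pairs()].
#' @return a tibble `family, category, isolate, reference,
#'   isolate_count, reference_count, flagged`.
#' @export
flag_enrichment <- function(table, pairs = canola_reference_pairs()) {
  stopifnot(inherits(table, "cazome_table"))
  genomes <- unique(table$genome)
  unknown <- setdiff(c(names(pairs), unname(pairs)), genomes)
  if (length(unknown) > 0) {
    stop("genome id(s) not in the table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(names(pairs), function(iso) {
    ref <- pairs[[iso]]
    iso_rows <- table[table$genome == iso, ]
    ref_rows <- table[table$genome == ref, ]
    key <- paste(ref_rows$family, ref_rows$category)
    ref_count <- ref_rows$count[match(paste(iso_rows$family,
                                            iso_rows$category), key)]
    tibble::tibble(
      family = iso_rows$family,
      category = iso_rows$category,
      isolate = iso,
      reference = ref,
      isolate_count = iso_rows$count,
      reference_count = ref_count,
      flagged = !is.na(ref_count) & iso_rows$count > ref_count
    )
  })
  do.call(rbind, rows)
}

#' Ratio of total CAZyme content between two genomes
#'
#' Grand total of genome `a` divided by grand total of genome `b`,
#' computed over the families present in the given table only (the scope
#' is recorded on the result — a table restricted to the major
#' plant-cell-wall families yields a table-scoped ratio, not a
#' genome-wide one).
#'
#' @param table a [cazome_table()].
#' @param genome_a,genome_b genome ids present in the table.
#' @return a single number with attributes `totals` and `scope`.
#' @export
cazome_ratio <- function(table, genome_a, genome_b) {
  stopifnot(inherits(table, "cazome_table"))
  totals <- aggregate_cazome(table)
  grand <- totals[totals$category == "Total", ]
  for (g in c(genome_a, genome_b)) {
    if (!g %in% grand$genome) {
      stop("genome id not in the table: ", g, call. = FALSE)
    }
  }
  ta <- grand$total[grand$genome == genome_a]
  tb <- grand$total[grand$genome == genome_b]
  if (tb == 0) stop("zero grand total for denominator genome ", genome_b,
                    call. = FALSE)
  structure(ta / tb,
            totals = stats::setNames(c(ta, tb), c(genome_a, genome_b)),
            scope = paste0("families listed in the supplied table only (",
                           length(unique(table$family)), " families)"))
}
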