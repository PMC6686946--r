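# Readers and writers for the standard formats the pipeline touches, and
# their normalisation into the internal data model.  Coordinate conventions:
# BED intervals are 0-based half-open; VCF and genetic-map positions are
# 1-based.  A 1-based site p lies in region [s, e) iff s < p <= e.

SEX_CHROMS <- c("chrX", "chrY", "X", "Y")

#' Read a sample-to-population panel
#'
#' Two-column TSV (`sample_id`, `population`), header required.
#'
#' @param path file path.
#' @return named character vector mapping sample id to population.
#' @export
read_panel <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(d)))
    stop("panel must have columns sample_id and population")
  if (anyDuplicated(d$sample_id)) stop("duplicate sample ids in panel")
  stats::setNames(d$population, d$sample_id)
}

#' Read phased biallelic genotypes from a VCF
#'
#' Parses a VCF 4.x file (via vcfR), keeps phased biallelic SNP records
#' (multi-allelic / non-SNP records are skipped and counted), optionally
#' applies a minor-allele-frequency filter (sites with MAF >= `maf_min` are
#' retained), and returns a [hap_matrix] with haplotype rows grouped by
#' individual in VCF sample order.
#'
#' @param path VCF path (plain text or gzip).
#' @param panel named character vector `sample_id -> population` (see
#'   [read_panel]); every VCF sample must be present.
#' @param maf_min MAF cutoff; 0 disables the filter.
#' @param block_records records parsed per block; cohort-scale files are
#'   read in blocks to keep the peak memory near the output matrix size.
#' @return a [hap_matrix]; the number of skipped non-biallelic-SNP records
#'   is attached as attribute `n_skipped`.
#' @export
read_vcf <- function(path, panel, maf_min = 0, block_records = 60000L) {
  # parse in record blocks: cohort-scale files would otherwise materialise
  # tens of millions of genotype strings at once, and R's node heap never
  # shrinks back after such a spike
  n_total <- local({  # stream-count data records (vcfR pads short reads)
    con <- gzfile(path, "r")
    on.exit(close(con))
    n <- 0L
    repeat {
      lines <- readLines(con, n = 100000L)
      if (!length(lines)) break
      n <- n + sum(!startsWith(lines, "#") & nzchar(lines))
    }
    n
  })
  if (n_total == 0L) stop("VCF contains no records")
  samples <- NULL
  n_skipped <- 0L
  chroms <- character(0)
  pos_blocks <- list()
  allele_blocks <- list()
  for (skip in seq.int(0L, n_total - 1L, by = block_records)) {
    v <- suppressWarnings(
      vcfR::read.vcfR(path, verbose = FALSE,
                      nrows = min(block_records, n_total - skip),
                      skip = skip))
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))  # single-record blocks come back dimensionless
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    if (nrow(fix) == 0) break
    ref <- fix[, "REF"]; alt <- fix[, "ALT"]
    ok <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
      nchar(ref) == 1 & nchar(alt) == 1 &
      ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    n_skipped <- n_skipped + sum(!ok)
    if (any(ok)) {
      chroms <- unique(c(chroms, unique(fix[ok, "CHROM"])))
      pos <- as.integer(fix[ok, "POS"])
      gt <- v@gt[ok, -1, drop = FALSE]
      strip_extras <- any(grepl(":", v@gt[ok, 1], fixed = TRUE))
      rm(v)
      if (is.null(samples)) {
        samples <- colnames(gt)
        miss <- setdiff(samples, names(panel))
        if (length(miss))
          stop("sample(s) missing from panel: ", paste(miss, collapse = ", "))
      }
      S <- nrow(gt); N <- ncol(gt)
      alleles <- matrix(0L, nrow = 2 * N, ncol = S)
      for (j in seq_len(N)) {
        g <- gt[, j]
        if (strip_extras) g <- sub(":.*$", "", g)  # GT is the leading field
        unphased <- grepl("/", g, fixed = TRUE)
        if (any(unphased))
          stop(sprintf("unphased genotype at %s:%d sample %s",
                       chroms[1], pos[which(unphased)[1]], samples[j]))
        a1 <- substr(g, 1, 1); a2 <- substr(g, 3, 3)
        bad <- !(a1 %in% c("0", "1")) | !(a2 %in% c("0", "1"))
        if (any(bad))
          stop(sprintf("unsupported genotype '%s' at %s:%d sample %s",
                       g[which(bad)[1]], chroms[1], pos[which(bad)[1]],
                       samples[j]))
        alleles[2L * j - 1L, ] <- as.integer(a1)
        alleles[2L * j, ] <- as.integer(a2)
      }
      rm(gt)
      pos_blocks[[length(pos_blocks) + 1]] <- pos
      allele_blocks[[length(allele_blocks) + 1]] <- alleles
    }
    if (n_total > block_records) gc(verbose = FALSE)
  }
  if (n_skipped > 0)
    message("read_vcf: skipped ", n_skipped, " non-biallelic-SNP record(s)")
  if (length(pos_blocks) == 0) stop("no biallelic SNP records in VCF")
  if (length(chroms) != 1)
    stop("VCF must contain a single chromosome, found: ",
         paste(chroms, collapse = ", "))
  chrom <- chroms
  pos <- unlist(pos_blocks)
  alleles <- do.call(cbind, allele_blocks)
  rm(allele_blocks)

  if (maf_min > 0) {
    f <- colMeans(alleles)
    keep <- pmin(f, 1 - f) >= maf_min
    alleles <- alleles[, keep, drop = FALSE]
    pos <- pos[keep]
  }
  if (length(pos) == 0) stop("no sites left after filtering")
  h <- hap_matrix(alleles, pos, chrom = chrom,
                  hap_pop = rep(unname(panel[samples]), each = 2),
                  sample_ids = samples)
  attr(h, "n_skipped") <- n_skipped
  h
}

#' Region set
#'
#' Internal tabular form of a set of genomic regions with tissue and
#' organ-system membership: a data.frame with columns `chrom`, `start`,
#' `end` (0-based half-open), `region_id`, and list-columns `tissues` and
#' `organ_systems`.
#'
#' @param chrom,start,end,region_id vectors of equal length.
#' @param tissues list of character vectors (non-empty) per region.
#' @param organ_map named character vector `tissue -> organ system`.
#' @return a data.frame of class `region_set`.
#' @export
region_set <- function(chrom, start, end, region_id, tissues, organ_map) {
  if (any(start >= end)) stop("region start must be < end")
  unknown <- setdiff(unique(unlist(tissues)), names(organ_map))
  if (length(unknown))
    stop("unknown tissue label(s): ", paste(unknown, collapse = ", "))
  if (any(lengths(tissues) == 0)) stop("every region needs >= 1 tissue")
  if (anyDuplicated(region_id)) stop("duplicate region ids")
  tissues <- unname(tissues)
  organ_systems <- lapply(tissues, function(tt) unique(unname(organ_map[tt])))
  d <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), region_id = as.character(region_id),
                  stringsAsFactors = FALSE)
  d$tissues <- lapply(tissues, as.character)
  d$organ_systems <- organ_systems
  class(d) <- c("region_set", "data.frame")
  d
}

#' Read a tissue map
#'
#' TSV with header columns `region_id` and `tissues` (comma-separated
#' labels).
#'
#' @param path file path.
#' @return named list `region_id -> character vector of tissues`.
#' @export
read_tissue_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("region_id", "tissues") %in% names(d)))
    stop("tissue map must have columns region_id and tissues")
  stats::setNames(strsplit(d$tissues, ",", fixed = TRUE), d$region_id)
}

#' Read an organ-system map
#'
#' TSV with header columns `tissue` and `organ_system`.
#'
#' @param path file path.
#' @return named character vector `tissue -> organ system`.
#' @export
read_organ_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("tissue", "organ_system") %in% names(d)))
    stop("organ map must have columns tissue and organ_system")
  stats::setNames(d$organ_system, d$tissue)
}

#' Read regions from a BED file
#'
#' BED3+ (0-based half-open); column 4, when present, is the region id.
#' Regions on sex chromosomes are excluded; a region whose id is missing
#' from the tissue map, or whose tissue is missing from the organ map, is an
#' error.
#'
#' @param path BED path.
#' @param tissue_map named list `region_id -> tissues` (see
#'   [read_tissue_map]).
#' @param organ_map named character vector `tissue -> organ system`.
#' @return a [region_set].
#' @export
read_bed_regions <- function(path, tissue_map, organ_map) {
  d <- utils::read.table(path, header = FALSE, sep = "",
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(d) < 3) stop("BED needs at least 3 columns")
  chrom <- as.character(d[[1]])
  start <- suppressWarnings(as.integer(d[[2]]))
  end <- suppressWarnings(as.integer(d[[3]]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop("invalid interval (start >= end) at BED line ", bad[1])
  ids <- if (ncol(d) >= 4) as.character(d[[4]]) else
    sprintf("region_%05d", seq_along(chrom))
  keep <- !(chrom %in% SEX_CHROMS)
  if (!any(keep)) stop("no autosomal regions in BED")
  chrom <- chrom[keep]; start <- start[keep]; end <- end[keep]; ids <- ids[keep]
  miss <- setdiff(ids, names(tissue_map))
  if (length(miss))
    stop("region id(s) missing from tissue map: ", paste(miss, collapse = ", "))
  region_set(chrom, start, end, ids, tissue_map[ids], organ_map)
}

#' Read a HapMap-format genetic map
#'
#' Whitespace- or comma-delimited columns: position (1-based), rate (cM/Mb),
#' cumulative cM; a header line is tolerated.
#'
#' @param path file path.
#' @return a [genetic_map].
#' @export
read_genetic_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (any(grepl(",", lines[1], fixed = TRUE))) "," else ""
  first <- strsplit(trimws(lines[1]), if (sep == ",") "," else "[ \t]+")[[1]]
  skip <- if (suppressWarnings(anyNA(as.numeric(first[1:3])))) 1 else 0
  d <- utils::read.table(text = lines, header = FALSE, sep = sep, skip = skip,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("genetic map needs 3 columns: position, rate, cumulative cM")
  if (nrow(d) < 2) stop("genetic map needs at least 2 points")
  genetic_map(d[[1]], d[[2]], d[[3]])
}

# ---- metric table -----------------------------------------------------------

METRIC_TABLE_COLS <- c("region_id", "tissue", "metric", "population",
                       "value", "p_empirical", "significant", "reason")

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))

#' Write / read a metric table
#'
#' Long-format TSV with columns `region_id`, `tissue`, `metric`,
#' `population`, `value`, `p_empirical`, `significant` (plus a trailing
#' `reason` column preserving NA reason codes).  Numeric values are written
#' with 12 significant digits; NA is written as the literal `NA`.
#'
#' @param table a metric-table data.frame.
#' @param path output path.
#' @return (write) the path, invisibly; (read) the data.frame.
#' @export
write_metric_table <- function(table, path) {
  for (cn in setdiff(METRIC_TABLE_COLS, names(table)))
    table[[cn]] <- if (cn == "significant") NA else NA_character_
  out <- data.frame(region_id = table$region_id, tissue = table$tissue,
                    metric = table$metric, population = table$population,
                    value = fmt_num(table$value),
                    p_empirical = fmt_num(table$p_empirical),
                    significant = ifelse(is.na(table$significant), "NA",
                                         ifelse(table$significant, "TRUE", "FALSE")),
                    reason = ifelse(is.na(table$reason), "NA", table$reason),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(METRIC_TABLE_COLS, collapse = "\t"), con)
  if (nrow(out))
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA",
                         colClasses = c(region_id = "character",
                                        tissue = "character",
                                        metric = "character",
                                        population = "character",
                                        value = "numeric",
                                        p_empirical = "numeric",
                                        significant = "logical",
                                        reason = "character"))
  d
}

# ---- writers used by the synthetic-data generator ---------------------------

#' Write a haplotype matrix as a phased VCF
#'
#' Minimal VCF 4.2 text: fileformat and contig header lines plus phased GT
#' records (REF A, ALT T placeholders for synthetic biallelic sites).
#'
#' @param h a [hap_matrix].
#' @param path output path.
#' @param contig_length declared contig length (default: max position).
#' @export
write_vcf <- function(h, path, contig_length = NULL) {
  if (is.null(contig_length)) contig_length <- max(h$positions, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", h$chrom,
                       as.integer(contig_length)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", h$sample_ids), collapse = "\t")), con)
  S <- n_sites(h)
  if (S > 0) {
    A <- h$alleles
    odd <- seq(1, nrow(A), by = 2)
    # emit in site chunks so cohort-scale matrices never materialise the
    # whole body at once
    chunk <- 20000L
    for (off in seq.int(1L, S, by = chunk)) {
      idx <- off:min(S, off + chunk - 1L)
      k <- length(idx)
      gt_cols <- lapply(seq_along(odd), function(i)
        paste0(A[odd[i], idx], "|", A[odd[i] + 1, idx]))
      fixed <- list(rep(h$chrom, k), h$positions[idx],
                    sprintf("%s_%d", h$chrom, h$positions[idx]),
                    rep("A", k), rep("T", k), rep(".", k), rep("PASS", k),
                    rep(".", k), rep("GT", k))
      writeLines(do.call(paste, c(fixed, gt_cols, sep = "\t")), con)
    }
  }
  invisible(path)
}

#' Write a panel TSV
#' @param h a [hap_matrix].
#' @param path output path.
#' @export
write_panel <- function(h, path) {
  odd <- seq(1, length(h$hap_pop), by = 2)
  utils::write.table(data.frame(sample_id = h$sample_ids,
                                population = h$hap_pop[odd]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a region set as BED + tissue map + organ map
#' @param regions a [region_set].
#' @param bed_path,tissue_map_path,organ_map_path output paths.
#' @param organ_map named character vector `tissue -> organ system`.
#' @export
write_regions <- function(regions, bed_path, tissue_map_path,
                          organ_map_path = NULL, organ_map = NULL) {
  utils::write.table(regions[, c("chrom", "start", "end", "region_id")],
                     bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(region_id = regions$region_id,
                                tissues = vapply(regions$tissues, paste,
                                                 "", collapse = ",")),
                     tissue_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(organ_map_path)) {
    if (is.null(organ_map)) stop("organ_map required with organ_map_path")
    utils::write.table(data.frame(tissue = names(organ_map),
                                  organ_system = unname(organ_map)),
                       organ_map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(bed_path)
}

#' Write a genetic map TSV
#' @param map a [genetic_map].
#' @param path output path.
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(data.frame(position = map$positions,
                                rate_cM_Mb = fmt_num(map$rate),
                                cM = fmt_num(map$cumulative_cM)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait-association SNP catalog
#'
#' TSV with header columns `rsid`, `chrom`, `position` (1-based), `trait`.
#'
#' @param path file path.
#' @return data.frame of class `snp_catalog`.
#' @export
read_snp_catalog <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  need <- c("rsid", "chrom", "position", "trait")
  if (!all(need %in% names(d))) stop("catalog must have columns ",
                                     paste(need, collapse = ", "))
  if (any(d$position < 1)) stop("catalog positions must be >= 1")
  if (anyDuplicated(d[, c("chrom", "position", "trait", "rsid")]))
    stop("duplicate catalog records")
  class(d) <- c("snp_catalog", "data.frame")
  d
}
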