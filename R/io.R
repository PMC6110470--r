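# File-format codecs. Internal coordinate convention everywhere: 1-based
# inclusive start, exclusive end, length = end - start. BED (0-based
# half-open) and GFF3/VCF (1-based inclusive) are converted at the boundary:
# internal start = bed_start + 1 = gff_start, internal end = bed_end + 1 =
# gff_end + 1.

#' Write a depth matrix as TSV
#'
#' First column `sample`, one column per target named `chrom:start-end`.
#'
#' @param cohort List with `depth` (matrix) and `targets`.
#' @param path Output file.
#' @export
write_depth_tsv <- function(cohort, path) {
  df <- as_tibble(cohort$depth, .name_repair = "minimal")
  names(df) <- cohort$targets$target
  df <- bind_cols(tibble(sample = rownames(cohort$depth)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a depth matrix TSV
#'
#' @param path Input file (format of [write_depth_tsv()]).
#' @param samples Optional tibble (sample, phenotype) to attach.
#' @return List with `depth`, `samples`, `targets` (class `exodel_cohort`).
#' @export
read_depth_tsv <- function(path, samples = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(df)[1] != "sample") {
    abort(sprintf("%s: first column must be 'sample', found '%s'",
                  path, names(df)[1]))
  }
  targets <- parse_target_ids(names(df)[-1])
  depth <- as.matrix(df[, -1])
  rownames(depth) <- df$sample
  if (is.null(samples)) {
    samples <- tibble(sample = df$sample, phenotype = NA_character_)
  }
  structure(list(depth = depth, samples = samples, targets = targets,
                 truth = NULL, config = NULL), class = "exodel_cohort")
}

#' Write CNV calls as an XCNV-style TSV
#'
#' Columns: SAMPLE, CNV, INTERVAL, KB, MID_BP, NUM_TARG, Q_SOME, Z_MEAN
#' (plus PHENOTYPE when present).
#'
#' @param calls Scored calls tibble.
#' @param path Output file.
#' @export
write_calls_tsv <- function(calls, path) {
  out <- tibble(
    SAMPLE = calls$sample,
    CNV = calls$type,
    INTERVAL = sprintf("%s:%d-%d", calls$chrom, as.integer(calls$start),
                       as.integer(calls$end)),
    KB = round((calls$end - calls$start) / 1000, 3),
    MID_BP = floor((calls$start + calls$end) / 2),
    NUM_TARG = calls$n_targets,
    Q_SOME = calls$q_some,
    Z_MEAN = calls$z_mean
  )
  if ("phenotype" %in% names(calls)) out$PHENOTYPE <- calls$phenotype
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read an XCNV-style calls TSV
#'
#' @param path Input file.
#' @return Calls tibble (sample, chrom, start, end, type, n_targets,
#'   z_mean, q_some, length_bp, phenotype if present).
#' @export
read_calls_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("SAMPLE", "CNV", "INTERVAL", "NUM_TARG", "Q_SOME", "Z_MEAN")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  iv <- parse_target_ids(df$INTERVAL)
  out <- tibble(sample = df$SAMPLE, chrom = iv$chrom, start = iv$start,
                end = iv$end, type = df$CNV,
                n_targets = as.integer(df$NUM_TARG),
                z_mean = df$Z_MEAN, q_some = as.integer(df$Q_SOME))
  out$length_bp <- out$end - out$start
  if ("PHENOTYPE" %in% names(df)) out$phenotype <- df$PHENOTYPE
  out
}

#' Write intervals as BED (0-based half-open)
#'
#' @param x Tibble with chrom/start/end (internal convention) and optional
#'   `name` and `score`-like extra column.
#' @param path Output file.
#' @param name_col,score_col Optional column names for BED fields 4-5.
#' @export
write_bed <- function(x, path, name_col = NULL, score_col = NULL) {
  out <- tibble(chrom = x$chrom, start = as.integer(x$start - 1),
                end = as.integer(x$end - 1))
  if (!is.null(name_col)) out$name <- x[[name_col]]
  if (!is.null(score_col)) out$score <- x[[score_col]]
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file into internal coordinates
#'
#' @param path Input file; tab-separated, no header, >= 3 columns.
#' @param extra_names Names for columns beyond chrom/start/end.
#' @return Tibble with 1-based inclusive-start, exclusive-end coordinates.
#' @export
read_bed <- function(path, extra_names = NULL) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        comment = "#")
  if (ncol(df) < 3) abort(sprintf("%s: BED needs >= 3 columns", path))
  bad <- which(!is.numeric(df[[2]]) | !is.numeric(df[[3]]) | df[[2]] >= df[[3]])
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: BED requires numeric start < end", path, bad[1]))
  }
  out <- tibble(chrom = as.character(df[[1]]), start = df[[2]] + 1,
                end = df[[3]] + 1)
  extras <- df[, -(1:3), drop = FALSE]
  if (ncol(extras) > 0) {
    names(extras) <- extra_names %||% paste0("col", 4:(3 + ncol(extras)))
    out <- bind_cols(out, extras)
  }
  out
}

#' Read gene models from BED or GFF3 (auto-detected by extension)
#'
#' BED: columns chrom, start, end, symbol (4th). GFF3: `gene` feature rows
#' with `Name=` or `ID=` attributes; 1-based inclusive coordinates
#' converted to the internal convention.
#'
#' @param path Input `.bed`, `.gff`, or `.gff3` file.
#' @return Tibble: symbol, chrom, start, end (internal convention).
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    df <- read_bed(path, extra_names = "symbol")
    if (!"symbol" %in% names(df)) abort(sprintf("%s: gene BED needs a name column", path))
    return(df[, c("symbol", "chrom", "start", "end")])
  }
  if (!ext %in% c("gff", "gff3")) {
    abort(sprintf("%s: unsupported gene-model extension '%s'", path, ext))
  }
  df <- readr::read_tsv(path, col_names = c("chrom", "source", "feature",
                                            "start", "end", "score", "strand",
                                            "frame", "attributes"),
                        comment = "#", show_col_types = FALSE)
  genes <- df %>% filter(.data$feature == "gene")
  sym <- stringr::str_match(genes$attributes, "(?:Name|ID)=([^;]+)")[, 2]
  if (anyNA(sym)) abort(sprintf("%s: gene rows lacking Name=/ID= attribute", path))
  tibble(symbol = sym, chrom = as.character(genes$chrom),
         start = genes$start, end = genes$end + 1)
}

#' Read a reference CNV frequency map (BED + frequency column)
#'
#' @param path BED-like TSV whose 4th column is a frequency in \[0, 1\].
#' @return Tibble: chrom, start, end (internal convention), frequency.
#' @export
read_reference_map <- function(path) {
  df <- read_bed(path, extra_names = "frequency")
  if (!"frequency" %in% names(df) || !is.numeric(df$frequency) ||
      any(df$frequency < 0 | df$frequency > 1)) {
    abort(sprintf("%s: 4th column must be a frequency in [0, 1]", path))
  }
  df
}

#' Write a reference CNV frequency map
#' @param map Tibble (chrom, start, end, frequency), internal coordinates.
#' @param path Output file.
#' @export
write_reference_map <- function(map, path) {
  write_bed(map, path, score_col = "frequency")
}

#' Read gene sets from GMT
#'
#' @param path GMT file (set name, description, then symbols, tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    abort(sprintf("%s: line %d: GMT rows need name, description and >= 1 gene",
                  path, bad[1]))
  }
  setNames(lapply(parts, function(p) p[-(1:2)]),
           vapply(parts, `[[`, character(1), 1))
}

#' Write gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write an interaction network (edge list + node attributes)
#'
#' @param network `exodel_network`.
#' @param edges_path Two-column TSV of edges.
#' @param nodes_path TSV of node attributes (gene, brain_expressed).
#' @export
write_network_tsv <- function(network, edges_path, nodes_path) {
  readr::write_tsv(network$edges, edges_path)
  readr::write_tsv(network$nodes, nodes_path)
  invisible(edges_path)
}

#' Read an interaction network from TSVs
#'
#' @param edges_path Two-column TSV (from, to).
#' @param nodes_path Optional node-attribute TSV (gene, brain_expressed);
#'   when absent, nodes are inferred from the edges with
#'   `brain_expressed = TRUE`.
#' @return An `exodel_network`.
#' @export
read_network_tsv <- function(edges_path, nodes_path = NULL) {
  edges <- readr::read_tsv(edges_path, show_col_types = FALSE)
  if (ncol(edges) < 2) abort(sprintf("%s: edge list needs 2 columns", edges_path))
  names(edges)[1:2] <- c("from", "to")
  if (!is.null(nodes_path)) {
    nodes <- readr::read_tsv(nodes_path, show_col_types = FALSE)
    if (!all(c("gene", "brain_expressed") %in% names(nodes))) {
      abort(sprintf("%s: node table needs gene and brain_expressed columns",
                    nodes_path))
    }
  } else {
    nodes <- tibble(gene = sort(unique(c(edges$from, edges$to))),
                    brain_expressed = TRUE)
  }
  orphan <- setdiff(unique(c(edges$from, edges$to)), nodes$gene)
  if (length(orphan) > 0) {
    abort(sprintf("%s: edge endpoint(s) missing from node table: %s",
                  edges_path, paste(head(orphan, 3), collapse = ", ")))
  }
  new_network(nodes, edges[, c("from", "to")])
}

VCF_INFO_KEYS <- c(
  GENE = "gene", EFFECT = "effect",
  SIFT = "sift", PP2HDIV = "pp2_hdiv", PP2HVAR = "pp2_hvar", LRT = "lrt",
  MUTTASTER = "mutation_taster", MUTASSESSOR = "mutation_assessor",
  FATHMM = "fathmm", METASVM = "metasvm", METALR = "metalr",
  CADD = "cadd", GERP = "gerp", PHYLOP = "phylop", SIPHY = "siphy",
  AF_KG = "af_kg", AF_EXAC = "af_exac", AF_EVS = "af_evs",
  AF_DBSNP = "af_dbsnp",
  QD = "qd", FS = "fs", MQ = "mq", MQRANKSUM = "mq_rank_sum",
  READPOSRANKSUM = "read_pos_rank_sum", SITEDP = "dp_site",
  GQMEAN = "gq_mean", VQSLOD = "vqslod", ABHET = "abhet",
  HWEPHRED = "hwe_phred", MISSINGNESS = "missingness"
)

#' Write an annotated variant table as VCF
#'
#' Site annotations go into INFO keys, per-sample genotypes into
#' `GT:DP:GQ` FORMAT fields; non-carrier samples are written `0/0`,
#' QC-masked genotypes `./.`. The `deleterious` flag and fired `criteria`
#' are emitted as `DELETERIOUS` / `CRITERIA` INFO entries when present.
#'
#' @param variants `exodel_variants` (sites + genotypes).
#' @param path Output `.vcf`.
#' @param samples Sample IDs forming the genotype columns (default: those
#'   seen in the genotypes, sorted).
#' @export
write_variants_vcf <- function(variants, path, samples = NULL) {
  sites <- variants$sites
  geno <- variants$genotypes
  if (is.null(samples)) samples <- sort(unique(geno$sample))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=exodel",
    vapply(names(VCF_INFO_KEYS), function(k) sprintf(
      '##INFO=<ID=%s,Number=1,Type=String,Description="%s">', k,
      VCF_INFO_KEYS[[k]]), character(1)),
    '##INFO=<ID=DELETERIOUS,Number=0,Type=Flag,Description="composite deleteriousness verdict">',
    '##INFO=<ID=CRITERIA,Number=.,Type=String,Description="fired deleteriousness criteria">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  info_for <- function(i) {
    kv <- character(0)
    for (k in names(VCF_INFO_KEYS)) {
      col <- VCF_INFO_KEYS[[k]]
      if (col %in% names(sites) && !is.na(sites[[col]][i])) {
        kv <- c(kv, paste0(k, "=", format(sites[[col]][i], digits = 10,
                                          scientific = FALSE, trim = TRUE)))
      }
    }
    if ("deleterious" %in% names(sites) && isTRUE(sites$deleterious[i])) {
      kv <- c(kv, "DELETERIOUS")
    }
    if ("criteria" %in% names(sites) && length(sites$criteria[[i]]) > 0) {
      kv <- c(kv, paste0("CRITERIA=", paste(sites$criteria[[i]], collapse = ",")))
    }
    if (length(kv) == 0) "." else paste(kv, collapse = ";")
  }
  gt_map <- split(geno, geno$variant_id)
  rows <- vapply(seq_len(nrow(sites)), function(i) {
    g <- gt_map[[sites$variant_id[i]]]
    cells <- rep("0/0:.:.", length(samples))
    if (!is.null(g)) {
      pos <- match(g$sample, samples)
      cells[pos[!is.na(pos)]] <- sprintf(
        "%s:%d:%d", if_else(is.na(g$gt), "./.", g$gt), g$dp, g$gq)[!is.na(pos)]
    }
    paste(c(sites$chrom[i], as.integer(sites$pos[i]), sites$variant_id[i],
            sites$ref[i], sites$alt[i], ".", "PASS", info_for(i), "GT:DP:GQ",
            cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an annotated VCF back into an `exodel_variants` object
#'
#' Parses the INFO/FORMAT keys written by [write_variants_vcf()]. Uses the
#' `vcfR` parser.
#'
#' @param path Input `.vcf`.
#' @return `exodel_variants` with `sites` and `genotypes` tibbles.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sites <- tibble(
    variant_id = fix$ID, chrom = fix$CHROM, pos = as.numeric(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  info <- fix$INFO
  get_info <- function(key) {
    m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    m
  }
  numeric_cols <- setdiff(names(VCF_INFO_KEYS), c("GENE", "EFFECT"))
  pred_keys <- c("SIFT", "PP2HDIV", "PP2HVAR", "LRT", "MUTTASTER",
                 "MUTASSESSOR", "FATHMM", "METASVM", "METALR")
  sites$gene <- get_info("GENE")
  sites$effect <- get_info("EFFECT")
  for (k in pred_keys) sites[[VCF_INFO_KEYS[[k]]]] <- get_info(k)
  for (k in setdiff(numeric_cols, pred_keys)) {
    sites[[VCF_INFO_KEYS[[k]]]] <- as.numeric(get_info(k))
  }
  sites$deleterious <- stringr::str_detect(info, "(^|;)DELETERIOUS(;|$)")
  crit <- get_info("CRITERIA")
  sites$criteria <- purrr::map(crit, function(x)
    if (is.na(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]])
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  geno <- tibble(
    variant_id = rep(sites$variant_id, ncol(gt)),
    sample = rep(colnames(gt), each = nrow(gt)),
    gt = as.vector(gt),
    dp = as.integer(as.vector(dp)),
    gq = as.integer(as.vector(gq))
  ) %>% filter(!is.na(.data$gt) | !is.na(.data$dp))
  geno <- geno %>% filter(is.na(.data$gt) | .data$gt != "0/0")
  geno$gt[!is.na(geno$gt) & geno$gt == "./."] <- NA_character_
  structure(list(sites = sites, genotypes = geno), class = "exodel_variants")
}

#' Read a YAML pipeline/simulation configuration
#' @param path YAML file.
#' @return Named list.
#' @export
read_yaml_config <- function(path) {
  yaml::read_yaml(path)
}
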