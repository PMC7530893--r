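# Mapping phase-locking states onto reference functional-network labels and
# extracting seed-region connectivity views.

#' Generate a synthetic region table
#'
#' A stand-in for a real parcellation table (which users supply for real
#' data): region ids, names, MNI-like coordinates drawn uniformly in a brain
#' -sized box, a 13-network reference label (including an "Uncertain"
#' category) and a 7-network alternative label. Entirely synthetic and
#' deterministic given the seed.
#'
#' @param n_regions number of regions (default 223).
#' @param seed integer seed.
#' @return tibble: region_id, name, mni_x, mni_y, mni_z, network_13,
#'   network_7.
#' @export
synthetic_region_table <- function(n_regions = 223, seed = 1L) {
  nets13 <- c("DefaultMode", "DorsalAttention", "VentralAttention",
              "Frontoparietal", "CinguloOpercular", "Salience",
              "Sensorimotor", "Auditory", "Visual", "MemoryRetrieval",
              "Subcortical", "Cerebellar", "Uncertain")
  nets7 <- c("Default", "DorsalAttention", "VentralAttention",
             "Frontoparietal", "Limbic", "Somatomotor", "Visual")
  with_seed(seed, {
    n13 <- sample(nets13, n_regions, replace = TRUE)
    n7 <- sample(nets7, n_regions, replace = TRUE)
    tibble::tibble(
      region_id = seq_len(n_regions),
      name = sprintf("region_%03d", seq_len(n_regions)),
      mni_x = round(runif(n_regions, -70, 70)),
      mni_y = round(runif(n_regions, -105, 70)),
      mni_z = round(runif(n_regions, -45, 75)),
      network_13 = n13,
      network_7 = n7
    )
  })
}

#' Read a region table from TSV
#'
#' Columns: region_id, name, mni_x, mni_y, mni_z, network_13 and optionally
#' network_7; rows must align with the series matrices' row order. The
#' package ships a synthetic example at
#' `system.file("extdata", "region_table_synthetic.tsv", package = "plstates")`.
#'
#' @param path TSV file path.
#' @return a tibble.
#' @export
read_region_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("region_id", "name", "mni_x", "mni_y", "mni_z", "network_13")
  abort_if(!all(need %in% names(tab)),
           paste("region table must have columns:",
                 paste(need, collapse = ", ")))
  abort_if(anyDuplicated(tab$region_id) > 0, "region ids must be unique")
  tab
}

#' Overlap of a state's communities with reference networks
#'
#' For each reference network, the Pearson correlation between a binary
#' community-membership indicator derived from the centroid (positive
#' elements for the smallest community, negative for the largest) and the
#' network's binary membership vector, with its p value. With
#' `weighted = TRUE` the indicator carries the centroid magnitudes instead.
#'
#' @param vc sign-conventioned centroid (length = regions).
#' @param region_table tibble with a `reference` column of network labels.
#' @param reference column name, `"network_7"` (default) or `"network_13"`.
#' @param weighted use centroid magnitudes instead of binary indicators.
#' @param sig_level flag threshold (default 0.001).
#' @return tibble: community, network, r, p, significant.
#' @export
rsn_overlap <- function(vc, region_table, reference = "network_7",
                        weighted = FALSE, sig_level = 0.001) {
  abort_if(!reference %in% names(region_table),
           sprintf("reference column '%s' missing from region table",
                   reference))
  abort_if(length(vc) != nrow(region_table),
           "centroid length must equal region-table rows")
  labels <- region_table[[reference]]
  nets <- sort(unique(labels))
  purrr::map_dfr(c("smallest", "largest"), function(comm) {
    memb <- if (comm == "smallest") vc > 0 else vc <= 0
    ind <- if (weighted) abs(vc) * memb else as.numeric(memb)
    purrr::map_dfr(nets, function(net) {
      y <- as.numeric(labels == net)
      if (stats::sd(ind) == 0 || stats::sd(y) == 0) {
        return(tibble::tibble(community = comm, network = net,
                              r = NA_real_, p = NA_real_,
                              significant = FALSE))
      }
      ct <- stats::cor.test(ind, y)
      tibble::tibble(community = comm, network = net,
                     r = unname(ct$estimate), p = ct$p.value,
                     significant = ct$p.value < sig_level)
    })
  })
}

#' Connections of seed regions within a state's communities
#'
#' For each community of the centroid, lists the edges from every seed
#' region to each other region of the same community, annotated with both
#' endpoints' network labels.
#'
#' @param vc sign-conventioned centroid.
#' @param region_table region table aligned with `vc`.
#' @param seed_names character; matched against the table's `name` column
#'   (substring match, case-insensitive).
#' @param reference network-label column used for annotation.
#' @return tibble: community, seed_id, seed_name, seed_network, other_id,
#'   other_name, other_network.
#' @export
seed_edges <- function(vc, region_table, seed_names,
                       reference = "network_13") {
  abort_if(length(vc) != nrow(region_table),
           "centroid length must equal region-table rows")
  hits <- unique(unlist(lapply(seed_names, function(s) {
    grep(s, region_table$name, ignore.case = TRUE)
  })))
  abort_if(length(hits) == 0,
           sprintf("no region matches seed name(s): %s",
                   paste(seed_names, collapse = ", ")))
  cs <- community_split(vc)
  template <- tibble::tibble(
    community = character(), seed_id = integer(), seed_name = character(),
    seed_network = character(), other_id = integer(),
    other_name = character(), other_network = character()
  )
  dplyr::bind_rows(template, purrr::map_dfr(c("smallest", "largest"), function(comm) {
    memb <- cs[[comm]]
    seeds_here <- intersect(hits, memb)
    purrr::map_dfr(seeds_here, function(sd) {
      others <- setdiff(memb, sd)
      if (length(others) == 0) return(tibble::tibble())
      tibble::tibble(
        community = comm,
        seed_id = region_table$region_id[sd],
        seed_name = region_table$name[sd],
        seed_network = region_table[[reference]][sd],
        other_id = region_table$region_id[others],
        other_name = region_table$name[others],
        other_network = region_table[[reference]][others]
      )
    })
  }))
}
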