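#' Reference MEI biomarker degree table
#'
#' The published degree table of the 22 ranked metabolic biomarkers from a
#' depression plasma-metabolomics MEI network (36 biomarkers x 350 enzymes):
#' HMDB accession, metabolite name, enzyme degree, detection platform and
#' concentration trend in patients. Fourteen of these biomarkers have degree
#' strictly greater than 10, the hub rule's worked example.
#'
#' @return data.frame: `id`, `name`, `degree`, `platform`, `trend`.
#' @export
ref_mei_biomarker_degrees <- function() {
  df <- data.frame(
    id = c("HMDB0034146", "HMDB0004610", "HMDB0000123", "HMDB0000641",
           "HMDB0000097", "HMDB0000122", "HMDB0000094", "HMDB0010393",
           "HMDB0010383", "HMDB0010396", "HMDB0010384", "HMDB0000161",
           "HMDB0000159", "HMDB0000294", "HMDB0000883", "HMDB0003681",
           "HMDB0000190", "HMDB0000925", "HMDB0002329", "HMDB0000099",
           "HMDB0001494", "HMDB0060348"),
    name = c("Stearic acid", "Phytosphingosine", "Glycine", "Glutamine",
             "Choline", "Glucose", "Citrate", "LPC 10:3", "LPC 16:1",
             "LPC 21:4", "LPC 18:0", "Alanine", "Phenylalanine", "Urea",
             "Valine", "4-Acetamidobutanoic acid", "Lactate", "TMAO",
             "Oxalic acid", "L-Cystathionine", "Acetylphosphate",
             "4-oxohex-2-enedioic acid"),
    degree = c(72L, 44L, 41L, 32L, 30L, 29L, 25L, 25L, 25L, 25L, 25L, 21L,
               19L, 12L, 7L, 6L, 5L, 5L, 2L, 2L, 2L, 1L),
    platform = c("GC-MS", "LC-MS", "1H-NMR", "1H-NMR", "1H-NMR", "1H-NMR",
                 "1H-NMR", "LC-MS", "LC-MS", "LC-MS", "LC-MS", "1H-NMR",
                 "1H-NMR", "GC-MS", "multiple", "LC-MS", "1H-NMR", "1H-NMR",
                 "GC-MS", "LC-MS", "LC-MS", "LC-MS"),
    trend = c("up", "up", "down", "up", "down", "down", "down", "up", "up",
              "up", "up", "down", "down", "down", "down", "down", "up",
              "up", "up", "down", "down", "down"),
    stringsAsFactors = FALSE
  )
  df$role <- "biomarker"
  df[order(-df$degree, df$id), c("id", "name", "role", "degree", "platform",
                                 "trend")]
}

#' Reference MEI enzyme degree table
#'
#' The published table of 31 important enzymes from the same MEI analysis:
#' UniProt accession, name, biomarker degree and function categories
#' (semicolon-separated in the source, a character vector here). Hydrolases
#' dominate, followed by transferases and acyltransferases.
#'
#' @return data.frame: `id`, `name`, `degree`, plus list column `functions`.
#' @export
ref_mei_enzyme_degrees <- function() {
  df <- data.frame(
    id = c("O15496", "O60733", "P04054", "P0C869", "P39877", "P47712",
           "Q6P1J6", "Q86U10", "Q9BZM2", "Q9NZ20", "Q9NZK7", "Q9UNK4",
           "Q15102", "O75608", "O95372", "P04180", "P68402", "Q13093",
           "Q6P1A2", "Q7L5N7", "Q8NCC3", "Q8NF37", "Q99487", "Q14032",
           "P06276", "Q13510", "Q16773", "Q5QJU3", "Q8TDN7", "Q969I3",
           "Q9HCG7"),
    name = c("Group 10 secretory phospholipase A2",
             "85/88 kDa calcium-independent phospholipase A2",
             "Phospholipase A2", "Cytosolic phospholipase A2 beta",
             "Calcium-dependent phospholipase A2",
             "Cytosolic phospholipase A2",
             "Phospholipase B1, membrane-associated",
             "60 kDa lysophospholipase",
             "Group IIF secretory phospholipase A2",
             "Group 3 secretory phospholipase A2",
             "Group IIE secretory phospholipase A2",
             "Group IID secretory phospholipase A2",
             "Platelet-activating factor acetylhydrolase IB subunit gamma",
             "Acyl-protein thioesterase 1", "Acyl-protein thioesterase 2",
             "Phosphatidylcholine-sterol acyltransferase",
             "Platelet-activating factor acetylhydrolase IB subunit beta",
             "Platelet-activating factor acetylhydrolase",
             "Lysophospholipid acyltransferase 5",
             "Lysophosphatidylcholine acyltransferase 2",
             "Group XV phospholipase A2",
             "Lysophosphatidylcholine acyltransferase 1",
             "Platelet-activating factor acetylhydrolase 2, cytoplasmic",
             "Bile acid-CoA:amino acid N-acyltransferase", "Cholinesterase",
             "Acid ceramidase", "Kynurenine-oxoglutarate transaminase 1",
             "Alkaline ceramidase 2", "Alkaline ceramidase 1",
             "Glycine N-acyltransferase-like protein 1",
             "Non-lysosomal glucosylceramidase"),
    degree = c(rep(5L, 12L), rep(4L, 11L), rep(2L, 7L), 2L),
    stringsAsFactors = FALSE
  )
  funs <- c(
    rep(list("Hydrolase"), 6),
    list(c("Acyltransferase", "Transferase")),
    rep(list("Hydrolase"), 5),
    rep(list("Hydrolase"), 3),
    list(c("Acyltransferase", "Transferase")),
    rep(list("Hydrolase"), 2),
    list(c("Acyltransferase", "Transferase")),
    list(c("Acyltransferase", "Transferase")),
    list(c("Acyltransferase", "Hydrolase", "Transferase")),
    list(c("Acyltransferase", "Transferase")),
    list("Hydrolase"),
    list(c("Acyltransferase", "Hydrolase", "Serine esterase", "Transferase")),
    list(c("Hydrolase", "Serine esterase")),
    list("Hydrolase"),
    list(c("Aminotransferase", "Lyase", "Transferase")),
    list("Hydrolase"), list("Hydrolase"),
    list(c("Acyltransferase", "Transferase")),
    list(c("Glycosidase", "Hydrolase"))
  )
  df$functions <- funs
  df$role <- "enzyme"
  df[order(-df$degree, df$id),
     c("id", "name", "role", "degree", "functions")]
}

#' The nine targets shared by all three systems in the reference study
#'
#' UniProt accessions of the targets (TP53, IL1B, TNF, PTEN, HLA-DRB1,
#' MTOR, HRAS, INS, PIK3CA) reported active in the nervous, immune and
#' endocrine MTI networks simultaneously.
#'
#' @return character vector of nine UniProt accessions, sorted.
#' @export
ref_shared_targets <- function() {
  sort(c("P04637", "P01584", "P01375", "P60484", "P01911", "P42345",
         "P01112", "P01308", "P42336"))
}
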