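#' Entity-type registries for cardiogenic-stroke diagnosis evidence
#'
#' Two registries are used throughout the package.  The *default* (modeling)
#' registry holds the 11 entity types actually tagged by the sequence model:
#' the ten most frequent diagnosis evidences / potential evidences of
#' cardiogenic stroke observed in echocardiograph reports, plus the compound
#' aortic-and-mitral-valve calcification evidence.  The *full* registry adds
#' the remaining transthoracic-echocardiography evidence classes from the
#' clinician-curated catalogue (20 evidence classes in total), so that lexicon
#' files referring to the rarer classes still validate.
#'
#' Each registry row carries a short ASCII `code`, the canonical Chinese
#' surface (`surface_zh`), an English gloss (`gloss_en`) and a `category`
#' among `"evidence"`, `"potential"` (findings closely associated with, but
#' not themselves, a cardiac source of embolism) and `"compound"` (the single
#' combined aortic+mitral calcification class).
#'
#' @return A data frame with columns `code`, `surface_zh`, `gloss_en`,
#'   `category`, one row per entity type.  `entity_types()` returns the 11
#'   modeled types in descending corpus-frequency order; `all_entity_types()`
#'   returns the full catalogue (24 rows).
#' @examples
#' entity_types()$code
#' nrow(all_entity_types())
#' @export
entity_types <- function() {
  et <- data.frame(
    code = c(
      "cardiac_enlargement", "aortic_calcification", "myocardial_infarction",
      "mitral_calcification", "wall_hypokinesis", "systolic_dysfunction",
      "prosthetic_valve", "mitral_stenosis", "mural_thrombus",
      "mitral_prolapse", "aortic_mitral_calcification"
    ),
    surface_zh = c(
      "心脏增大",
      "主动脉瓣钙化",
      "心肌梗死",
      "二尖瓣钙化",
      "室壁运动减弱",
      "心脏收缩功能减弱",
      "人工瓣膜及心内辅助装置",
      "二尖瓣狭窄",
      "左室附壁血栓",
      "二尖瓣脱垂",
      "主动脉瓣、二尖瓣钙化"
    ),
    gloss_en = c(
      "cardiac enlargement", "aortic valve calcification",
      "myocardial infarction", "mitral valve calcification",
      "ventricular wall hypokinesis", "decrease of systolic heart function",
      "prosthetic valves and devices", "mitral stenosis",
      "left ventricular mural thrombus", "mitral valve prolapse",
      "aortic and mitral valve calcification"
    ),
    category = c(
      "potential", "evidence", "evidence", "evidence", "potential",
      "potential", "evidence", "evidence", "evidence", "evidence", "compound"
    ),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(et$code), nrow(et) == 11L)
  et
}

#' @rdname entity_types
#' @export
all_entity_types <- function() {
  extra <- data.frame(
    code = c(
      "ventricular_aneurysm", "dilated_cardiomyopathy", "valvular_endocarditis",
      "intracardiac_mass", "myxoma", "papillary_fibroelastoma",
      "low_ejection_fraction", "apex_dyskinesia", "spontaneous_echo_contrast",
      "lambl_excrescence", "atrial_septal_aneurysm", "atrial_septal_defect",
      "congestive_heart_failure"
    ),
    surface_zh = c(
      "左心室室壁瘤",
      "扩张型心肌病",
      "瓣膜性心内膜炎",
      "心内肿物",
      "粘液瘤",
      "乳头状弹力纤维瘤",
      "射血分数<35%",
      "左心室尖运动障碍",
      "自显影",
      "巨大Lambl's赘生物",
      "房间隔瘤",
      "房间隔缺损",
      "充血性心力衰竭"
    ),
    gloss_en = c(
      "left ventricular aneurysm", "dilated cardiomyopathy",
      "valvular endocarditis", "intracardiac mass", "myxoma",
      "papillary fibroelastoma", "ejection fraction < 35%",
      "left ventricular apex dyskinesia", "spontaneous echo contrast",
      "giant Lambl's excrescences", "atrial septal aneurysm",
      "atrial septal defect", "congestive heart failure"
    ),
    category = rep("evidence", 13L),
    stringsAsFactors = FALSE
  )
  rbind(entity_types(), extra)
}

#' BIO label scheme over an entity-type registry
#'
#' Builds the tag set `{B-t, I-t : t in types} + {O}` used by the sequence
#' model, together with the augmented START/STOP indices that frame the CRF
#' transition matrix.  With the default 11-type registry this yields
#' `k = 2 * 11 + 1 = 23` emission labels; transitions live in a
#' `(k + 2) x (k + 2)` matrix whose last two rows/columns are START and STOP.
#'
#' @param types Entity-type registry data frame (default [entity_types()]),
#'   or a character vector of type codes.
#' @return A list of class `label_scheme` with elements `types` (codes),
#'   `tags` (character vector, `O` first, length `k`), `k`, and 1-based
#'   augmented indices `start` (= k + 1) and `stop` (= k + 2).
#' @examples
#' scheme <- label_scheme()
#' scheme$k   # 23
#' @export
label_scheme <- function(types = entity_types()) {
  codes <- if (is.data.frame(types)) types$code else as.character(types)
  stopifnot(length(codes) > 0L, !anyDuplicated(codes))
  tags <- c("O", as.vector(rbind(paste0("B-", codes), paste0("I-", codes))))
  k <- length(tags)
  structure(
    list(types = codes, tags = tags, k = k, start = k + 1L, stop = k + 2L),
    class = "label_scheme"
  )
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("BIO label scheme: ", length(x$types), " entity types, k = ", x$k,
      " labels (+ START/STOP)\n", sep = "")
  invisible(x)
}

tag_index <- function(tags, scheme) {
  idx <- match(tags, scheme$tags)
  if (anyNA(idx)) {
    stop("unknown tag label(s): ",
         paste(unique(tags[is.na(idx)]), collapse = ", "))
  }
  idx
}
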