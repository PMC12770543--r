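#' Deterministic rule-based part-of-speech tagger
#'
#' A closed-class lexicon plus suffix heuristics, with NOUN as the default
#' open-class tag. Deliberately simple and fully deterministic: the idea
#' density feature only needs a stable split between proposition-bearing tags
#' (verbs, adjectives, adverbs, adpositions, conjunctions) and the rest.
#' Auxiliaries are tagged VERB, matching the convention that "is" in
#' "the boy is falling" carries a proposition.
#'
#' @param tokens Character vector of lowercase word tokens.
#' @return Character vector of tags, one per token, from
#'   {DET, PRON, VERB, ADJ, ADV, ADP, CONJ, NUM, INTJ, NOUN}.
#' @export
pos_tag <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  lex <- pos_lexicon()
  tags <- rep(NA_character_, length(tokens))
  for (tag in names(lex)) {
    hit <- is.na(tags) & tokens %in% lex[[tag]]
    tags[hit] <- tag
  }
  open <- is.na(tags)
  if (any(open)) {
    tk <- tokens[open]
    guess <- rep("NOUN", length(tk))
    guess[endsWith(tk, "ly")] <- "ADV"
    verbish <- endsWith(tk, "ing") | endsWith(tk, "ed") |
      endsWith(tk, "s") & !endsWith(tk, "ss") & nchar(tk) > 3L &
      (endsWith(tk, "es") | endsWith(tk, "hes"))
    guess[verbish & guess == "NOUN"] <- "VERB"
    adjish <- endsWith(tk, "ful") | endsWith(tk, "ous") | endsWith(tk, "ive") |
      endsWith(tk, "able") | endsWith(tk, "ible") | endsWith(tk, "ish") |
      endsWith(tk, "est")
    guess[adjish & guess == "NOUN"] <- "ADJ"
    tags[open] <- guess
  }
  tags
}

pos_lexicon <- function() {
  list(
    DET = c("a", "an", "the", "this", "that", "these", "those", "each",
            "every", "some", "any", "no", "all", "both", "half"),
    PRON = c("i", "me", "my", "mine", "myself", "we", "us", "our", "ours",
             "you", "your", "yours", "he", "him", "his", "she", "her", "hers",
             "they", "them", "their", "theirs", "it", "its", "who", "whom",
             "whose", "what", "which", "something", "anything", "nothing",
             "everything", "somebody", "anybody", "nobody", "everyone",
             "it's", "that's", "there's"),
    VERB = c("am", "is", "are", "was", "were", "be", "been", "being", "have",
             "has", "had", "do", "does", "did", "will", "would", "can",
             "could", "shall", "should", "may", "might", "must", "go", "goes",
             "went", "gone", "come", "comes", "came", "get", "gets", "got",
             "see", "sees", "saw", "seen", "look", "looks", "looked", "fall",
             "falls", "fell", "falling", "run", "runs", "ran", "running",
             "take", "takes", "took", "taken", "stand", "stands", "stood",
             "reach", "reaches", "reached", "wash", "washes", "washed",
             "spill", "spills", "spilled", "climb", "climbs", "climbed",
             "say", "says", "said", "know", "knows", "knew", "think",
             "thinks", "thought", "want", "wants", "wanted", "dry", "dries",
             "dried", "overflow", "overflows", "overflowing", "steal",
             "steals", "stole", "laugh", "laughs", "laughed", "wobble",
             "wobbles", "wobbling", "tip", "tips", "tipping"),
    ADJ = c("little", "small", "big", "tall", "short", "young", "old", "wet",
            "full", "empty", "high", "low", "busy", "quiet", "happy", "sad",
            "dirty", "clean", "open", "closed", "good", "bad", "nice",
            "pretty", "sweet", "heavy", "light", "hot", "cold", "hard",
            "soft", "strong", "weak", "enough", "whole", "complete", "done",
            "tired", "many", "much", "few", "several", "more", "most",
            "less", "other", "another", "same", "different"),
    ADV = c("very", "really", "just", "so", "there", "here", "now", "then",
            "quite", "rather", "almost", "always", "never", "often",
            "sometimes", "again", "also", "too", "away", "back", "still",
            "already", "maybe", "perhaps", "not", "n't", "up", "down", "out",
            "off", "over", "well", "actually", "basically", "anyway",
            "like"),
    ADP = c("in", "on", "at", "by", "with", "from", "into", "onto", "under",
            "above", "below", "near", "beside", "behind", "through",
            "during", "about", "of", "to", "for", "between", "around",
            "against", "toward", "upon", "inside", "outside"),
    CONJ = c("and", "but", "or", "because", "although", "while", "if",
             "when", "since", "unless", "whereas", "however", "though",
             "as"),
    NUM = c("one", "two", "three", "four", "five", "six", "seven", "eight",
            "nine", "ten", "first", "second", "third", "dozen", "couple"),
    INTJ = c("oh", "ah", "wow", "oops", "ouch", "hey", "gosh", "gee", "uh",
             "um", "er", "hm", "hmm", "erm", "mm", "uhm", "yes", "yeah",
             "yep", "ok", "okay", "alright", "uh_huh")
  )
}

#' Tags counted as proposition-bearing for idea density
#' @return Character vector of tags.
#' @keywords internal
proposition_tags <- function() c("VERB", "ADJ", "ADV", "ADP", "CONJ")
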