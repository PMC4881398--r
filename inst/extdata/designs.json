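{
  "sturt_exp1": {
    "description": "Two-sentence design; the inaccessible referent is the matrix subject of the critical sentence (a pronoun coreferent with a name in the context sentence), the accessible referent is the embedded-clause subject. Critical sentence: 'He remembered that the surgeon had pricked himself'.",
    "reflexive_word_index": 7,
    "referents": {
      "accessible": {
        "label": "surgeon",
        "role": "subject",
        "clause": "current",
        "mention_word_indices": [4],
        "context_sentence_mention": false
      },
      "inaccessible": {
        "label": "pronoun",
        "role": "subject",
        "clause": "other",
        "mention_word_indices": [0],
        "context_sentence_mention": true
      }
    }
  },
  "sturt_exp2": {
    "description": "One critical sentence with a subject relative clause; the inaccessible referent is the object inside the relative clause. Critical sentence: 'The surgeon who treated Jonathan had pricked himself'.",
    "reflexive_word_index": 7,
    "referents": {
      "accessible": {
        "label": "surgeon",
        "role": "subject",
        "clause": "current",
        "mention_word_indices": [1],
        "context_sentence_mention": false
      },
      "inaccessible": {
        "label": "name",
        "role": "object",
        "clause": "other",
        "mention_word_indices": [4],
        "context_sentence_mention": true
      }
    }
  },
  "modified": {
    "description": "Object relative clause; the inaccessible referent is the relative-clause subject, sharing the subject role with the accessible matrix subject and sitting closer to the reflexive. Critical sentence: 'The tough soldier that Katie treated in the military hospital introduced himself to all the nurses'.",
    "reflexive_word_index": 11,
    "referents": {
      "accessible": {
        "label": "soldier",
        "role": "subject",
        "clause": "current",
        "mention_word_indices": [2],
        "context_sentence_mention": false
      },
      "inaccessible": {
        "label": "name",
        "role": "subject",
        "clause": "other",
        "mention_word_indices": [4],
        "context_sentence_mention": false
      }
    }
  }
}
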