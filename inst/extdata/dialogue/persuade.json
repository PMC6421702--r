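{
  "strategy": "persuade",
  "turns": [
    {
      "id": "greet",
      "speaker": "agent",
      "text": "Hello, I am here to talk with you about your sleeping problems.",
      "next_id": "severity_check"
    },
    {
      "id": "severity_check",
      "speaker": "agent",
      "text": "First, how severe would you say your situation is at the moment?",
      "expect": { "type": "choice", "options": ["low", "medium", "high"] },
      "next_id": "stance_check"
    },
    {
      "id": "stance_check",
      "speaker": "agent",
      "text": "And how do you currently feel about seeing a human therapist for this?",
      "expect": { "type": "choice", "options": ["negative", "doubting", "positive"] },
      "next_id": "tips_offer"
    },
    {
      "id": "tips_offer",
      "speaker": "agent",
      "text": "Would you like a few tips that may help in the meantime?",
      "expect": { "type": "choice", "options": ["yes", "no"] },
      "branch": { "yes": "tips", "no": "persuade_message" },
      "default_branch": "yes",
      "next_id": "tips"
    },
    {
      "id": "tips",
      "speaker": "agent",
      "text": "Try to keep a regular sleep schedule, avoid screens late at night, and keep your bedroom dark and quiet.",
      "next_id": "persuade_message"
    },
    {
      "id": "persuade_message",
      "speaker": "agent",
      "text_by_concern": {
        "money": "I understand that a cost of around {money_problem_amount} feels like a lot. Many clinics offer sliding-scale fees and insurance often covers sleep treatment, so the real cost is usually much lower than people expect. Untreated sleeping problems also carry costs of their own.",
        "time": "I understand that travelling around {travel_problem_hours} hours is a real burden. Many therapists now offer video consultations, and a first intake is often a single visit, so the travel may matter less than it seems.",
        "stigma": "I understand you worry about what your {stigma_group} might think. A therapist is bound to confidentiality, so nobody needs to know unless you choose to tell them. Many people find the people around them far more supportive than they feared."
      },
      "next_id": "announce_facilitation"
    },
    {
      "id": "announce_facilitation",
      "speaker": "agent",
      "text": "Talking to a human therapist could really help you. I will give you the contact details of a clinic now, unless you would rather I did not.",
      "expect": { "type": "choice", "options": ["continue", "object"] },
      "branch": { "continue": "contact_details", "object": "accept_objection" },
      "default_branch": "continue",
      "next_id": "contact_details"
    },
    {
      "id": "contact_details",
      "speaker": "agent",
      "text": "You can reach a therapist at {contact_details}. They will be glad to hear from you.",
      "next_id": "end"
    },
    {
      "id": "accept_objection",
      "speaker": "agent",
      "text": "That is fine, the choice is yours. If you change your mind, you can ask me for the contact details at any time.",
      "next_id": "end"
    }
  ]
}
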