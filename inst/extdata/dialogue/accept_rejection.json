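{
  "strategy": "accept_rejection",
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
      "branch": { "yes": "tips", "no": "accept_message" },
      "default_branch": "yes",
      "next_id": "tips"
    },
    {
      "id": "tips",
      "speaker": "agent",
      "text": "Try to keep a regular sleep schedule, avoid screens late at night, and keep your bedroom dark and quiet.",
      "next_id": "accept_message"
    },
    {
      "id": "accept_message",
      "speaker": "agent",
      "text": "I hear that seeing a human therapist is not something you want right now, and that is completely okay. It is your choice, and you are welcome to keep talking with me whenever you like.",
      "next_id": "standing_offer"
    },
    {
      "id": "standing_offer",
      "speaker": "agent",
      "text": "If you ever change your mind, just ask and I will give you the contact details of a therapist. Would you like them now?",
      "expect": { "type": "choice", "options": ["request_details", "decline"] },
      "branch": { "request_details": "contact_details", "decline": "end" },
      "default_branch": "decline",
      "next_id": "end"
    },
    {
      "id": "contact_details",
      "speaker": "agent",
      "text": "Of course. You can reach a therapist at {contact_details}. They will be glad to hear from you.",
      "next_id": "end"
    }
  ]
}
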