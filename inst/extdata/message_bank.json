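[
  {"id": "prep-01", "category": "prequit_prep", "text": "Your quit date is coming up. List three reasons you want to quit and keep them on your phone."},
  {"id": "prep-02", "category": "prequit_prep", "text": "Before your quit date, get rid of cigarettes, lighters, and ashtrays at home, in your car, and at work."},
  {"id": "prep-03", "category": "prequit_prep", "text": "Plan what you will do during your usual smoking times. Have a substitute ready, like gum or a short walk."},
  {"id": "low-01", "category": "low_risk", "text": "Nice work staying on track. Every hour without a cigarette helps your body recover."},
  {"id": "low-02", "category": "low_risk", "text": "Keep your reasons for quitting in mind today. You are building a new routine."},
  {"id": "low-03", "category": "low_risk", "text": "Staying smoke-free saves money fast. Think about what you will do with it."},
  {"id": "urge-01", "category": "high_risk_urge", "text": "Urges pass within a few minutes whether or not you smoke. Ride it out: breathe slowly and count to sixty."},
  {"id": "urge-02", "category": "high_risk_urge", "text": "A strong urge is a signal to change what you are doing. Step away, drink some water, keep your hands busy."},
  {"id": "urge-03", "category": "high_risk_urge", "text": "Delay is your friend: tell yourself you can decide again in ten minutes. Most urges fade before then."},
  {"id": "stress-01", "category": "high_risk_stress", "text": "Feeling stressed? Try slow breathing: in for four counts, out for six, for two minutes."},
  {"id": "stress-02", "category": "high_risk_stress", "text": "Stress is a common trigger. A short walk or stretching can lower it without a cigarette."},
  {"id": "stress-03", "category": "high_risk_stress", "text": "Smoking does not remove what is stressing you. Name the stressor and one small step you can take on it."},
  {"id": "avail-01", "category": "high_risk_availability", "text": "Cigarettes nearby make quitting harder. Put them out of reach or give them to someone else."},
  {"id": "avail-02", "category": "high_risk_availability", "text": "Easy access is a top lapse trigger. Change your surroundings for a few minutes."},
  {"id": "avail-03", "category": "high_risk_availability", "text": "If cigarettes are easily available, move to a smoke-free spot and take your nicotine gum with you."},
  {"id": "motiv-01", "category": "high_risk_motivation", "text": "Motivation dips are normal. Reread your reasons for quitting; they have not changed."},
  {"id": "motiv-02", "category": "high_risk_motivation", "text": "Think of the people who want you to succeed. One cigarette now works against all your progress."},
  {"id": "motiv-03", "category": "high_risk_motivation", "text": "You do not have to feel motivated to stay quit for the next hour. Just get through this hour."},
  {"id": "lapse-01", "category": "lapse_recovery", "text": "A slip is not a failure. Think about what led up to it and plan for that situation next time."},
  {"id": "lapse-02", "category": "lapse_recovery", "text": "One cigarette does not undo your quit attempt. Get back on track starting right now."},
  {"id": "lapse-03", "category": "lapse_recovery", "text": "Treat the lapse as a learning experience. What would you do differently in that moment?"},
  {"id": "daily-01", "category": "daily_treatment", "text": "Your quit date is tomorrow. Review your quit plan tonight."},
  {"id": "daily-02", "category": "daily_treatment", "text": "Wear your nicotine patch every day, starting when you wake up."},
  {"id": "daily-03", "category": "daily_treatment", "text": "Check in with yourself tonight: what worked today, and what will you try tomorrow?"},
  {"id": "gum-01", "category": "gum_prompt", "text": "Chewing a piece of nicotine gum right now may reduce your risk for smoking. Will you chew a piece of nicotine gum right now?"},
  {"id": "gum-02", "category": "gum_prompt", "text": "Keep a piece of nicotine gum within reach for high-risk moments."},
  {"id": "gum-03", "category": "gum_prompt", "text": "Nicotine gum works best when you chew it slowly and park it against your cheek."}
]
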