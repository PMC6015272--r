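# Annual staff activities for maintenance and delivery of the web programme.
# hours_per_occasion aggregates persons (e.g. 2 persons x 30 min = 1.0 h);
# a working day is carried as 7.5 h. printed_cost is the invoiced/reported
# annual figure and is authoritative for totals; the formula
# hours_per_occasion x occasions_per_year x rate reproduces most rows.
activity,payment_basis,rate,hours_per_occasion,occasions_per_year,printed_cost
emails_newsletters_sms,grade6_staff,34,7.5,26,6675
librarian_review,fixed_contract,30,1,52,1560
patient_rep_feedback_on_review,cash_payment,18,1,26,468
forum_monitoring_patient_reps,cash_payment,18,1,26,468
forum_monitoring_staff,grade6_staff,34,1,26,890
clinical_team_website_interaction,gp,121,1,5,605
patient_rep_review_clinical_feedback,cash_payment,18,0.5,5,45
content_update_staff,grade6_staff,34,2,26,1780
content_update_clinical,gp,121,2,26,6292
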