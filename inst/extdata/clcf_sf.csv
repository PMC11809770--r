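# CLCF-SF: 15-item short form of the Challenge of Living with Cystic
# Fibrosis questionnaire (caregiver-reported treatment-burden measure).
# Structure: 5 core items (cc1-cc3 expert-chosen challenge items; cs1-cs2
# perceived-support items added to preserve content validity) plus 10
# GA-selected items; 13 items on a 5-point Likert scale, 2 on a 4-point
# scale; all scored from 1; totals range 15..73, higher = greater challenge.
# NOTE: the item `text` below is SYNTHETIC placeholder wording and the
# domain assignment of the GA-selected items is a reconstruction; the
# published source for the full item list is not redistributed here.
# ASSUMPTION (recorded per the packaging convention): the two 4-point items
# are taken to be the two perceived-support core items cs1 and cs2.
id,text,domain,n_categories,core,min_code,reverse
cc1,How well are you juggling the demands of CF care with the needs of the rest of your family?,maintaining_cf_routines,5,TRUE,1,FALSE
cc2,How well does your family as a whole handle the challenges of CF?,family_caregiving_challenges,5,TRUE,1,FALSE
cc3,How much does the responsibility of looking after a child with CF affect you?,family_caregiving_challenges,5,TRUE,1,FALSE
cs1,How supported do you feel by your local pharmacist?,perceived_support,4,TRUE,1,FALSE
cs2,How supported do you feel by the specialist CF team?,perceived_support,4,TRUE,1,FALSE
ga1,How much has CF care disrupted your family's daily routines?,family_caregiving_challenges,5,FALSE,1,FALSE
ga2,How much strain has CF care placed on relationships within your family?,family_caregiving_challenges,5,FALSE,1,FALSE
ga3,How much has caring for your child with CF limited time for other family members?,family_caregiving_challenges,5,FALSE,1,FALSE
ga4,How emotionally demanding do you find day-to-day CF care?,family_caregiving_challenges,5,FALSE,1,FALSE
ga5,How challenging is your child's response to their CF treatments?,child_challenge,5,FALSE,1,FALSE
ga6,How hard is it to keep your child engaged with their CF routines?,child_challenge,5,FALSE,1,FALSE
ga7,How difficult is it to fit the full treatment routine into each day?,maintaining_cf_routines,5,FALSE,1,FALSE
ga8,How hard is it to keep up CF routines when away from home?,maintaining_cf_routines,5,FALSE,1,FALSE
ga9,How difficult do you find managing changes to the treatment plan?,maintaining_cf_routines,5,FALSE,1,FALSE
ga10,How much do you worry about your child's current health?,worries_current_health,5,FALSE,1,FALSE
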