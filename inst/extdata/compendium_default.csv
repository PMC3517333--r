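code,label,category,mets
office_desk_work,Sitting desk work,work,1.5
writing_desk,Writing or paperwork at a desk,work,1.3
meeting_sitting,Attending a meeting seated,work,1.5
standing_service_work,Standing service or shop work,work,2.3
teaching_standing,Teaching while standing,work,2.5
light_assembly_work,Light assembly-line work,work,2.5
nursing_care_work,Nursing or care work,work,3.0
cooking_professional,Professional cooking,work,2.5
farm_work_general,General farm work,work,4.8
construction_work,General construction work,work,4.0
carrying_loads_work,Carrying moderate loads at work,work,4.5
cleaning_workplace,Cleaning the workplace,work,3.3
delivery_work_walking,Delivery rounds on foot,work,3.5
heavy_manual_labor,Heavy manual labor,work,6.0
driving_work_vehicle,Driving a work vehicle,work,2.0
childcare_work,Professional child care,work,3.0
walking_commute,Walking to or from work,commute,3.5
walking_brisk_commute,Brisk walking to or from work,commute,4.3
cycling_commute,Cycling to or from work,commute,6.8
driving_car_commute,Driving a car,commute,2.5
motorbike_commute,Riding a motorbike or scooter,commute,2.8
riding_bus_sitting,Riding a bus seated,commute,1.3
riding_train_standing,Standing on a train,commute,2.0
waiting_for_transport,Waiting for transport,commute,1.3
climbing_stairs_slow,Climbing stairs at a slow pace,commute,4.0
sleep,Sleeping,leisure,0.9
sitting_quietly,Sitting quietly,leisure,1.1
watching_tv,Watching television,leisure,1.0
reading,Reading,leisure,1.3
listening_music,Listening to music seated,leisure,1.3
talking_sitting,Conversation while seated,leisure,1.5
eating_sitting,Eating a meal seated,leisure,1.5
personal_care,Washing and dressing,leisure,2.0
bathing,Bathing,leisure,1.5
cooking_home,Cooking at home,leisure,2.0
washing_dishes,Washing dishes,leisure,1.8
laundry,Doing laundry,leisure,2.0
house_cleaning,General house cleaning,leisure,3.3
vacuuming,Vacuuming,leisure,3.3
shopping_grocery,Grocery shopping,leisure,2.3
gardening,Gardening,leisure,3.8
playing_with_children,Active play with children,leisure,3.5
child_care,Child care at home,leisure,2.5
walking_dog,Walking the dog,leisure,3.0
playing_cards_games,Playing cards or board games,leisure,1.5
video_games,Playing video games,leisure,1.0
internet_browsing,Browsing the internet,leisure,1.3
hobby_crafts,Hobby crafts,leisure,1.8
playing_instrument,Playing a musical instrument,leisure,2.0
strolling,Strolling at an easy pace,leisure,2.8
walking_leisure,Leisure walking,leisure,3.5
standing_light,Standing light activity,leisure,1.8
religious_activity_sitting,Seated religious activity,leisure,1.3
socializing_standing,Socializing while standing,leisure,2.0
diy_home_repair,Home repair or DIY,leisure,3.0
car_washing,Washing the car,leisure,3.5
walking_exercise,Walking for exercise,sports,4.3
brisk_walking_exercise,Brisk walking for exercise,sports,5.0
jogging,Jogging,sports,7.0
running,Running,sports,9.8
running_fast,Fast running,sports,11.0
cycling_sport,Sport cycling,sports,8.0
swimming_leisure,Leisurely swimming,sports,6.0
swimming_laps,Swimming laps,sports,8.3
tennis,Tennis,sports,7.3
badminton,Badminton,sports,5.5
table_tennis,Table tennis,sports,4.0
golf_walking,Golf carrying or pulling clubs,sports,4.8
baseball_softball,Baseball or softball,sports,5.0
soccer,Soccer,sports,7.0
basketball,Basketball,sports,6.5
volleyball,Volleyball,sports,4.0
hiking,Hiking,sports,6.0
calisthenics_light,Light calisthenics,sports,3.5
calisthenics_vigorous,Vigorous calisthenics,sports,8.0
resistance_training,Resistance training,sports,5.0
stretching,Stretching,sports,2.3
yoga,Yoga,sports,2.5
dancing,Dancing,sports,4.5
aerobics,Aerobics,sports,7.3
martial_arts,Martial arts,sports,10.3
skiing,Skiing,sports,7.0
bowling,Bowling,sports,3.0
fishing,Fishing,sports,3.5
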